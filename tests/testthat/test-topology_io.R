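count_section <- function(lines, name) {
  ## number of data lines in every block of one section type
  hits <- grep(sprintf("^\\[ %s \\]$", name), lines)
  total <- 0
  for (h in hits) {
    i <- h + 1
    while (i <= length(lines) && !grepl("^\\[", lines[i])) {
      ln <- sub(";.*$", "", lines[i])
      if (grepl("\\S", ln)) total <- total + 1
      i <- i + 1
    }
  }
  total
}

test_that("emitted HOONO topology carries the expected blocks", {
  txt <- write_species_topology(get_topology("HOONO"))
  expect_equal(count_section(txt, "atoms"), 5)
  expect_equal(count_section(txt, "constraints"), 4)
  expect_equal(count_section(txt, "angles"), 3)
  expect_equal(count_section(txt, "pairs"), 2)
  ## two GROMOS dihedrals: 2 + 4 term lines
  expect_equal(count_section(txt, "dihedrals"), 6)
})

test_that("emitted H2O2 topology uses RB dihedrals and no 1-4 pairs", {
  txt <- write_species_topology(get_topology("H2O2"))
  expect_equal(count_section(txt, "pairs"), 0)
  dih <- grep("  3  ", txt[grep("^\\s*\\d+\\s+\\d+\\s+\\d+\\s+\\d+\\s+3\\s", txt)],
              value = TRUE)
  expect_equal(count_section(txt, "dihedrals"), 1)
  expect_true(any(grepl("^\\s*1\\s+2\\s+3\\s+4\\s+3\\s", txt)))
  expect_error(write_species_topology(get_topology("H2O2"), variant = "99X"),
               "unknown variant")
})

test_that("species topologies survive a write-read round trip", {
  for (id in list_species()) {
    top <- get_topology(id)
    txt <- write_species_topology(top)
    back <- read_species_topology(txt)
    expect_equal(back$species, top$species)
    expect_equal(back$formal_charge, top$formal_charge)
    expect_equal(back$atoms$type, top$atoms$type)
    expect_equal(back$atoms$charge, top$atoms$charge)
    expect_equal(back$bonds[order(back$bonds$i, back$bonds$j),
                            c("i", "j", "b0", "constrained")],
                 top$bonds[order(top$bonds$i, top$bonds$j),
                           c("i", "j", "b0", "constrained")],
                 ignore_attr = TRUE)
    expect_equal(back$angles, top$angles, ignore_attr = TRUE)
    expect_equal(back$impropers, top$impropers, ignore_attr = TRUE)
    expect_equal(length(back$dihedrals), length(top$dihedrals))
    key <- function(d) paste(d$i, d$j, d$k, d$l)
    for (d in top$dihedrals) {
      match <- Filter(function(b) key(b) == key(d), back$dihedrals)
      expect_length(match, 1)
      if (d$type == "rb") expect_equal(match[[1]]$c, d$c)
      else expect_equal(match[[1]]$terms[, c("m", "phi0", "k")],
                        d$terms[, c("m", "phi0", "k")], ignore_attr = TRUE)
    }
    expect_equal(back$pairs14[, c("i", "j", "c6", "c12")],
                 top$pairs14[, c("i", "j", "c6", "c12")], ignore_attr = TRUE)
    expect_setequal(paste(back$exclusions$i, back$exclusions$j),
                    paste(top$exclusions$i, top$exclusions$j))
  }
})

test_that("emission is byte-stable under write-read-write", {
  for (id in c("HOONO", "HNO3", "N2O4")) {
    txt1 <- write_species_topology(get_topology(id))
    txt2 <- write_species_topology(read_species_topology(txt1))
    expect_identical(txt1, txt2)
  }
})

test_that("the reader rejects corrupted input loudly", {
  expect_error(read_species_topology(character()), "empty")
  expect_error(read_species_topology("   "), "empty")
  txt <- write_species_topology(get_topology("HNO3"))
  ## break neutrality: the parsed charges no longer sum to an integer
  bad <- sub("-0.571", "-0.471", txt, fixed = TRUE)
  expect_error(read_species_topology(bad), "sum")
  ## unknown directive
  expect_error(read_species_topology(c("[ bogus ]", "1 2 3")), "unknown")
  ## truncated atoms record
  bad2 <- txt
  i <- grep("^\\s*1\\s+OQ", bad2)[1]
  bad2[i] <- "1 OQ 1"
  expect_error(read_species_topology(bad2), "malformed")
})

test_that("nonbonded pair tables cover the selection matrix exactly once", {
  db <- ff_database()
  txt <- write_nonbonded_tables("53A6")
  n_rows <- count_section(txt, "nonbond_params")
  partners <- rownames(db$selection$i_slot)
  new_types <- colnames(db$selection$i_slot)
  ## unordered pairs: 56 partners x 4 + the 10 RONS-RONS combinations
  n_expected <- length(setdiff(partners, new_types)) * length(new_types) +
    choose(length(new_types), 2) + length(new_types)
  expect_equal(n_rows, n_expected)
  ## the OP-OQ entry carries the slot-(2,3) product (restrict to the
  ## nonbond_params section: pairtypes holds the 1-4 value instead)
  sec_start <- grep("^\\[ nonbond_params \\]$", txt)
  sec_end <- grep("^\\[ pairtypes \\]$", txt)
  nb <- txt[sec_start:(sec_end - 1)]
  row <- grep("^OP\\s+OQ\\s", nb, value = TRUE)
  expect_length(row, 1)
  expect_match(row, "2.379856e-06")
  p14row <- grep("^OP\\s+OQ\\s", txt[sec_end:length(txt)], value = TRUE)
  expect_match(p14row, "1.112556e-06")
})

test_that("53A6 and 54A7 tables differ only in ion rows and lipid naming", {
  t53 <- write_nonbonded_tables("53A6")
  t47 <- write_nonbonded_tables("54A7")
  norm47 <- gsub("\\bOEL\\b", "OML", gsub("\\bCH3p\\b", "CH3L", t47))
  d53 <- setdiff(t53, norm47)
  d47 <- setdiff(norm47, t53)
  ions <- "NA\\+|CL-"
  expect_true(all(grepl(ions, d53[!grepl("^;", d53)])))
  expect_true(all(grepl(ions, d47[!grepl("^;", d47)])))
  expect_gt(length(d53[!grepl("^;", d53)]), 0)
})
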