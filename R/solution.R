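## Solution-structure analyses of coordinate trajectories: radial
## distribution functions, first-shell cutoffs, ion-pairing degree of
## ionization, and synthetic frame generators for testing.

#' Construct a frame set
#'
#' @param frames list of frames; each a list with `xyz` (N x 3 positions,
#'   nm), `box` (orthorhombic edge lengths, nm) and `groups` (per-particle
#'   labels).
#' @return An object of class `rons_frames`.
#' @export
frame_set <- function(frames) {
  if (length(frames) < 1) stop("at least one frame required")
  for (fr in frames) {
    stopifnot(is.matrix(fr$xyz), ncol(fr$xyz) == 3,
              length(fr$box) == 3, all(fr$box > 0),
              length(fr$groups) == nrow(fr$xyz))
  }
  structure(list(frames = frames), class = "rons_frames")
}

## minimum-image pair distances between coordinate sets A (n x 3) and B
## (m x 3); self = TRUE returns the n(n-1)/2 unique intra-set distances.
.min_image_dists <- function(A, B, box, self = FALSE) {
  dxyz <- lapply(1:3, function(k) {
    d <- outer(A[, k], B[, k], "-")
    d - box[k] * round(d / box[k])
  })
  D <- sqrt(dxyz[[1]]^2 + dxyz[[2]]^2 + dxyz[[3]]^2)
  if (self) D[upper.tri(D)] else as.vector(D)
}

#' Radial distribution function between two particle groups
#'
#' Minimum-image pair histogram over all frames, normalized by the
#' ideal-gas expectation so that g(r) -> 1 for uncorrelated homogeneous
#' particles.
#'
#' @param frames a `rons_frames` (see [frame_set()]).
#' @param groupA,groupB group labels; identical labels give the intra-group
#'   RDF (self-pairs excluded).
#' @param bin_width histogram bin width, nm (default 0.002).
#' @param r_max histogram range, nm; must not exceed half the smallest box
#'   edge (default: that bound).
#' @return Data frame of class `rons_rdf` with columns `r` (bin centers),
#'   `g` and `count`; attributes `bin_width` and `n_frames`.
#' @export
compute_rdf <- function(frames, groupA, groupB, bin_width = 0.002,
                        r_max = NULL) {
  frs <- frames$frames
  min_edge <- min(vapply(frs, function(f) min(f$box), 0))
  if (is.null(r_max)) r_max <- min_edge / 2
  if (r_max > min_edge / 2 + 1e-12)
    stop("r_max exceeds half the smallest box edge")
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1)
  norm <- numeric(length(breaks) - 1)
  shell_vol <- 4 / 3 * pi * diff(breaks^3)
  for (fr in frs) {
    ia <- which(fr$groups == groupA)
    ib <- which(fr$groups == groupB)
    if (length(ia) == 0 || length(ib) == 0) stop("empty particle group")
    same <- identical(groupA, groupB)
    d <- if (same) .min_image_dists(fr$xyz[ia, , drop = FALSE],
                                    fr$xyz[ia, , drop = FALSE], fr$box,
                                    self = TRUE)
         else .min_image_dists(fr$xyz[ia, , drop = FALSE],
                               fr$xyz[ib, , drop = FALSE], fr$box)
    counts <- counts + graphics::hist(d[d < r_max], breaks = breaks,
                                      plot = FALSE)$counts
    V <- prod(fr$box)
    npairs <- if (same) length(ia) * (length(ia) - 1) / 2
              else length(ia) * length(ib)
    norm <- norm + npairs / V * shell_vol
  }
  out <- data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    g = ifelse(norm > 0, counts / norm, 0),
                    count = counts)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- length(frs)
  class(out) <- c("rons_rdf", class(out))
  out
}

#' First-shell distance cutoff from an RDF
#'
#' Position of the first local minimum following the global first peak,
#' after light smoothing (fixed three-bin moving average).
#'
#' @param rdf a `rons_rdf` (or data frame with `r` and `g`).
#' @return Cutoff distance, nm.
#' @export
first_shell_cutoff <- function(rdf) {
  g <- stats::filter(rdf$g, rep(1 / 3, 3), sides = 2)
  g[1] <- rdf$g[1]; g[length(g)] <- rdf$g[length(g)]
  g <- as.numeric(g)
  ipk <- which.max(g)
  if (ipk >= length(g) - 1 || max(g) <= g[length(g)] + 1e-12 ||
      stats::sd(rdf$g) < 1e-12)
    stop("no first-shell structure: curve has no peak-then-minimum")
  after <- g[(ipk + 1):length(g)]
  imin <- NULL
  for (t in 2:(length(after) - 1)) {
    if (after[t] <= after[t - 1] && after[t] < after[t + 1]) { imin <- t; break }
  }
  if (is.null(imin)) stop("no local minimum after the first peak")
  rdf$r[ipk + imin]
}

#' Degree of ionization from ion-pair counting
#'
#' Frame-averaged fraction of ions with no counterion within the first-shell
#' cutoff (minimum-image distances).  An ion with one or more counterions
#' inside the cutoff counts as paired.
#'
#' @param frames a `rons_frames`.
#' @param ions,counterions group labels.
#' @param cutoff pairing distance cutoff, nm (> 0).
#' @return Fraction in \[0, 1\].
#' @export
degree_of_ionization <- function(frames, ions, counterions, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive")
  fracs <- vapply(frames$frames, function(fr) {
    ii <- which(fr$groups == ions)
    ic <- which(fr$groups == counterions)
    if (length(ii) == 0 || length(ic) == 0) stop("empty ion selection")
    D <- matrix(.min_image_dists(fr$xyz[ii, , drop = FALSE],
                                 fr$xyz[ic, , drop = FALSE], fr$box),
                nrow = length(ii))
    mean(apply(D, 1, min) > cutoff)
  }, 0)
  mean(fracs)
}

#' Generate synthetic frame fixtures
#'
#' Reproducible structured frame sets for testing the solution analyses
#' without molecular-dynamics trajectories:
#'
#' * `ideal_gas`: `n` uniformly random particles (group `"A"`) per frame;
#' * `paired_fraction`: `n` ions (group `"ion"`) and `n` counterions
#'   (`"counter"`) on a dilute grid, with a fraction `f` of the ions placed
#'   in contact (at `pair_distance`) with their counterion and the rest
#'   isolated far beyond `pair_distance`;
#' * `lattice`: a simple-cubic lattice of spacing `a` filling the box
#'   (group `"A"`).
#'
#' @param kind `"ideal_gas"`, `"paired_fraction"` or `"lattice"`.
#' @param n particle (or ion-pair) count per frame.
#' @param box cubic box edge, nm.
#' @param n_frames number of frames.
#' @param f paired fraction (paired_fraction kind); `f * n` must be integral.
#' @param pair_distance contact distance for paired ions, nm.
#' @param a lattice spacing, nm (lattice kind).
#' @param seed integer seed; identical seeds give identical frames.
#' @return A `rons_frames`.
#' @export
#' @examples
#' fs <- generate_fixture_frames("paired_fraction", n = 40, f = 0.25, seed = 1)
#' degree_of_ionization(fs, "ion", "counter", cutoff = 0.3)  # exactly 0.75
generate_fixture_frames <- function(kind = c("ideal_gas", "paired_fraction",
                                             "lattice"),
                                    n = 100, box = 5, n_frames = 1,
                                    f = 0.5, pair_distance = 0.25,
                                    a = 1, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    if (kind == "ideal_gas") {
      xyz <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
      groups <- rep("A", n)
    } else if (kind == "paired_fraction") {
      n_paired <- f * n
      if (abs(n_paired - round(n_paired)) > 1e-9)
        stop("f * n must be an integer")
      n_paired <- round(n_paired)
      ## place ion-pair sites on a coarse grid so sites never interfere
      ngrid <- ceiling((2 * n)^(1 / 3))
      spacing <- box / ngrid
      if (spacing < 4 * pair_distance)
        stop("infeasible packing: box too small for the requested count")
      idx <- seq_len(2 * n) - 1
      site <- cbind((idx %% ngrid),
                    (idx %/% ngrid) %% ngrid,
                    idx %/% (ngrid^2)) * spacing + spacing / 2
      ion_xyz <- site[seq_len(n), , drop = FALSE]
      ctr_xyz <- site[n + seq_len(n), , drop = FALSE]
      paired <- sample.int(n, n_paired)
      for (p in paired) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        ctr_xyz[p, ] <- (ion_xyz[p, ] + pair_distance * u) %% box
      }
      xyz <- rbind(ion_xyz, ctr_xyz)
      groups <- c(rep("ion", n), rep("counter", n))
    } else {
      m <- max(1, floor(box / a))
      g <- expand.grid(x = 0:(m - 1), y = 0:(m - 1), z = 0:(m - 1))
      xyz <- as.matrix(g) * a + a / 2
      groups <- rep("A", nrow(xyz))
      box <- m * a   # commensurate box
    }
    frames[[k]] <- list(xyz = xyz, box = rep(box, 3), groups = groups)
  }
  frame_set(frames)
}
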