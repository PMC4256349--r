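# Seeded generators for every input class the pipeline consumes: dipolar
# evolution traces, steady-state rate tables, stopped-flow transients,
# and synthetic dimer label-site fixtures. All generators are pure
# functions of their arguments and the seed.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a four-pulse PELDOR trace
#'
#' Generalises the refocused-echo modulation model
#' `V(t) = cos(2 pi nu_DD (t - tau))` to a multi-component,
#' partially-modulated signal over a smooth background:
#' \deqn{V(t) = B(t)\,[(1-\lambda) + \lambda \sum_i w_i K(r_i, t)]
#'       + \epsilon(t),}
#' where `K` is the powder-averaged dipolar kernel ([powder_kernel()]) or,
#' with `collapse_theta = TRUE`, the single-orientation perpendicular
#' cosine the basic model states; `B(t) = exp(-background * t)` is an
#' exponential background (flat by default) and the noise is additive
#' Gaussian with SD `noise_sd * mod_depth` (i.e. expressed as a fraction
#' of the modulation amplitude).
#'
#' @param components data.frame with columns `r_nm` and `weight`
#'   (weights must sum to 1)
#' @param mod_depth modulation depth lambda, in (0, 1] (default 0.3)
#' @param background exponential background decay rate, us^-1 (0 = flat)
#' @param noise_sd Gaussian noise SD as a fraction of the modulation
#'   amplitude (>= 0)
#' @param timing a [peldor_timing()]
#' @inheritParams spin_pair
#' @param seed integer seed; the trace is a pure function of the
#'   arguments and this seed
#' @param collapse_theta if TRUE, replace the orientation average by the
#'   perpendicular-orientation cosine
#' @return a [peldor_trace()]
#' @export
simulate_peldor <- function(components = data.frame(r_nm = 4.703,
                                                    weight = 1),
                            mod_depth = 0.3, background = 0, noise_sd = 0,
                            timing = peldor_timing(), g1 = G_FREE,
                            g2 = G_FREE, seed = 1,
                            collapse_theta = FALSE) {
  if (!all(c("r_nm", "weight") %in% names(components)))
    stop("components needs columns r_nm and weight", call. = FALSE)
  if (abs(sum(components$weight) - 1) > 1e-12)
    stop("component weights must sum to 1", call. = FALSE)
  if (mod_depth < 0 || mod_depth > 1)
    stop("mod_depth must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(inherits(timing, "peldor_timing"))
  t <- (seq_len(timing$n_points) - 1) * timing$dt
  K <- sapply(seq_len(nrow(components)), function(i) {
    r <- components$r_nm[i]
    if (collapse_theta)
      cos(2 * pi * perpendicular_frequency(r, g1, g2) *
          (t - timing$tau) * 1e-3)
    else powder_kernel(r, t, tau = timing$tau, g1 = g1, g2 = g2)
  })
  modul <- as.vector(K %*% components$weight)
  bg <- exp(-background * t * 1e-3)
  v <- bg * ((1 - mod_depth) + mod_depth * modul)
  if (noise_sd > 0)
    v <- v + .with_seed(seed, stats::rnorm(length(t), 0,
                                           noise_sd * mod_depth))
  peldor_trace(timing, v = v, t = t,
               provenance = sprintf("simulate_peldor seed=%s", seed))
}

#' Simulate replicated Michaelis--Menten datasets
#'
#' Rates `v = kcat * s / (Km + s) * (1 + e)`, `e ~ N(0, noise_cv)`,
#' drawn once per replicate on a fixed substrate design. The default
#' design is 10 concentrations spanning 10--2250 uM, the range used in a
#' coupled assay titration of a substrate from well below to well above
#' a Km near 190 uM.
#'
#' @param kcat turnover number, s^-1
#' @param Km Michaelis constant, uM
#' @param s_grid substrate concentrations, uM
#' @param noise_cv fractional (multiplicative) Gaussian noise SD
#' @param n_replicates number of independent datasets
#' @param seed integer seed
#' @return list of [mm_dataset()] objects, length `n_replicates`
#' @export
simulate_mm <- function(kcat = 2.97, Km = 189,
                        s_grid = c(10, 25, 50, 100, 250, 500, 750,
                                   1000, 1500, 2250),
                        noise_cv = 0.05, n_replicates = 1, seed = 1) {
  if (kcat <= 0 || Km <= 0) stop("kcat and Km must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  v0 <- kcat * s_grid / (Km + s_grid)
  .with_seed(seed, lapply(seq_len(n_replicates), function(i) {
    eps <- if (noise_cv > 0) stats::rnorm(length(s_grid), 0, noise_cv)
           else 0
    mm_dataset(s_grid, v0 * (1 + eps))
  }))
}

#' Simulate a stopped-flow absorbance transient
#'
#' `A(t) = a0 + amplitude * exp(-kobs * t) + e`, `e ~ N(0, noise_sd *
#' |amplitude|)`, on a uniform grid over the observation window. The
#' defaults describe a cobalamin Co--C bond homolysis transient: an
#' absorbance decrease at 528 nm (positive `amplitude` decaying towards
#' the `a0` baseline) observed for 0.25 s.
#'
#' @param kobs observed rate constant, s^-1
#' @param window observation window, s
#' @param n_points number of samples (>= 10)
#' @param amplitude signed absorbance change (positive = decay from
#'   above the baseline, i.e. a decrease over time)
#' @param a0 baseline absorbance
#' @param noise_sd Gaussian noise SD as a fraction of |amplitude|
#' @param seed integer seed
#' @return data.frame with columns `time` (s) and `A`
#' @export
simulate_stopped_flow <- function(kobs = 877, window = 0.25,
                                  n_points = 5000, amplitude = 0.05,
                                  a0 = 0.3, noise_sd = 0, seed = 1) {
  if (kobs <= 0) stop("kobs must be > 0", call. = FALSE)
  if (n_points < 10) stop("n_points must be >= 10", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  time <- seq(0, window, length.out = n_points)
  A <- a0 + amplitude * exp(-kobs * time)
  if (noise_sd > 0)
    A <- A + .with_seed(seed, stats::rnorm(n_points, 0,
                                           noise_sd * abs(amplitude)))
  data.frame(time = time, A = A)
}

# Synthetic dimer geometries embedding the distances the conformational
# models imply. Coordinates are constructed embeddings, not crystal
# coordinates. Open (resting) state: the measurable intra-monomer
# C700-C352 (49.0 A) and cross-dimer C352-C352' (29.0 A) pairs, with the
# C2-symmetric C700' placed so both cross pairs involving C700 exceed
# 60 A. Closed (radical-pair) state: cobalt centre at 19.0 A from C352
# (same half) and 31.0 A from C352' (other half); a second cobalt
# position at 17.0 A from C352 encodes the shorter of the two same-half
# readings (conformational heterogeneity).
.fixture_coords <- function(conformation) {
  # coordinates rounded to 0.001 A (PDB precision) so written fixtures
  # round-trip bit-identically; distance constraints hold to < 0.01 A
  round3 <- function(df) { df[c("x", "y", "z")] <- lapply(
    df[c("x", "y", "z")], round, digits = 3); df }
  round3(if (conformation == "open") {
    data.frame(
      name = c("C352", "C352'", "C700", "C700'"),
      chain = c("A", "B", "A", "B"),
      resno = c(352L, 352L, 700L, 700L),
      kind = "nitroxide_label",
      x = c(0, 29, -20, 49),
      y = c(0, 0, sqrt(49^2 - 20^2), -sqrt(49^2 - 20^2)),
      z = c(0, 0, 0, 0))
  } else {
    co <- c(4.155172413793103, sqrt(361 - 4.155172413793103^2), 0)
    co2 <- co / sqrt(sum(co^2)) * 17
    data.frame(
      name = c("C352", "C352'", "CO", "CO2"),
      chain = c("A", "B", "A", "A"),
      resno = c(352L, 352L, 900L, 901L),
      kind = c("nitroxide_label", "nitroxide_label", "cobalt_center",
               "cobalt_center"),
      x = c(0, 29, co[1], co2[1]),
      y = c(0, 0, co[2], co2[2]),
      z = c(0, 0, 0, 0))
  })
}

.pdb_line <- function(serial, record, atom, resname, chain, resno,
                      x, y, z, element) {
  sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, atom, resname, chain, resno, x, y, z, 1, 0,
          element)
}

#' Build a synthetic dimer label-site fixture
#'
#' Emits label sites realising the characteristic distances of the two
#' conformational models of a spin-labelled dimeric enzyme, and
#' optionally writes them as a valid PDB-format file (cysteine sites as
#' `SG` ATOM records, cobalt centres as `CO` HETATM records). The
#' geometries are synthetic embeddings honouring the stated distances to
#' better than 0.1 A by construction (verified at build time), not
#' crystallographic coordinates.
#'
#' * `"open"` (resting state): C700--C352 = 49.0 A, C352--C352' = 29.0 A,
#'   both cross-dimer pairs involving C700 > 60 A.
#' * `"closed"` (radical-pair state): cobalt--C352 = 19.0 A (same half,
#'   with a 17.0 A alternative position `CO2`), cobalt--C352' = 31.0 A.
#'
#' @param conformation `"open"` or `"closed"`
#' @param file optional path; when given, a PDB file is written there
#' @return a `label_sites` data.frame (invisible `file` attribute set
#'   when a file is written)
#' @export
make_dimer_fixture <- function(conformation = c("open", "closed"),
                               file = NULL) {
  conformation <- match.arg(conformation)
  sites <- .fixture_coords(conformation)
  # embedding feasibility check: the realised geometry must honour the
  # model distances it encodes
  d <- pairwise_distances(sites)
  key <- function(a, b) d$r_A[(d$site_a == a & d$site_b == b) |
                              (d$site_a == b & d$site_b == a)]
  target <- if (conformation == "open")
    c(key("C700", "C352") - 49, key("C352", "C352'") - 29)
  else c(key("CO", "C352") - 19, key("CO", "C352'") - 31,
         key("CO2", "C352") - 17)
  if (max(abs(target)) > 0.1)
    stop("fixture embedding failed its distance constraints", call. = FALSE)
  class(sites) <- c("label_sites", "data.frame")
  if (!is.null(file)) {
    lines <- vapply(seq_len(nrow(sites)), function(i) {
      metal <- sites$kind[i] == "cobalt_center"
      .pdb_line(i, if (metal) "HETATM" else "ATOM",
                if (metal) "CO" else "SG",
                if (metal) "CO " else "CYS",
                sites$chain[i], sites$resno[i],
                sites$x[i], sites$y[i], sites$z[i],
                if (metal) "CO" else "S")
    }, character(1))
    writeLines(c(sprintf(
      "REMARK   6 SYNTHETIC %s-conformation dimer label-site fixture",
      toupper(conformation)),
      "REMARK   6 coordinates are a constructed distance embedding",
      lines, "END"), file)
    attr(sites, "file") <- file
  }
  sites
}
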