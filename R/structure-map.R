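# Label-site distance prediction on structural models, PELDOR
# measurability rules, and reconciliation of measured distance
# assignments with open/closed conformations.

#' Read spin-label sites from a PDB coordinate file
#'
#' Resolves each selector to exactly one atom and copies its coordinates
#' verbatim. The default atom for cysteine label sites is the thiol
#' sulfur `SG`, the attachment point of methanethiosulfonate nitroxide
#' labels; the nitroxide midpoint itself lies several Angstrom further
#' out, so an outward offset along the CA->SG vector can be applied.
#'
#' @param pdb_file path to a PDB-format coordinate file
#' @param selection data.frame with columns `chain`, `resno`, and
#'   optionally `atom` (default `"SG"`), `kind` (default
#'   `"nitroxide_label"`; use `"cobalt_center"` for metal sites), and
#'   `name` (default `<chain><resno>`)
#' @param offset outward displacement along the CA->SG direction, Angstrom
#'   (default 0; ignored for non-SG selections or when CA is absent)
#' @return data.frame of class `label_sites` with columns `name`, `chain`,
#'   `resno`, `kind`, `x`, `y`, `z`
#' @export
read_sites <- function(pdb_file, selection, offset = 0) {
  if (!file.exists(pdb_file)) stop("no such PDB file: ", pdb_file,
                                   call. = FALSE)
  if (!all(c("chain", "resno") %in% names(selection)))
    stop("selection needs columns chain and resno", call. = FALSE)
  pdb <- bio3d::read.pdb(pdb_file)
  atoms <- pdb$atom
  n <- nrow(selection)
  atom <- if ("atom" %in% names(selection)) selection$atom else rep("SG", n)
  kind <- if ("kind" %in% names(selection)) selection$kind
          else rep("nitroxide_label", n)
  name <- if ("name" %in% names(selection)) selection$name
          else paste0(selection$chain, selection$resno)
  out <- lapply(seq_len(n), function(i) {
    hit <- which(atoms$chain == selection$chain[i] &
                 atoms$resno == selection$resno[i] &
                 atoms$elety == atom[i])
    if (length(hit) != 1)
      stop("selector (chain ", selection$chain[i], ", residue ",
           selection$resno[i], ", atom ", atom[i], ") resolved to ",
           length(hit), " atoms", call. = FALSE)
    pos <- as.numeric(atoms[hit, c("x", "y", "z")])
    if (offset != 0 && atom[i] == "SG") {
      ca <- which(atoms$chain == selection$chain[i] &
                  atoms$resno == selection$resno[i] & atoms$elety == "CA")
      if (length(ca) == 1) {
        dir <- pos - as.numeric(atoms[ca, c("x", "y", "z")])
        pos <- pos + offset * dir / sqrt(sum(dir^2))
      }
    }
    data.frame(name = name[i], chain = selection$chain[i],
               resno = selection$resno[i], kind = kind[i],
               x = pos[1], y = pos[2], z = pos[3])
  })
  out <- do.call(rbind, out)
  key <- paste(out$chain, out$resno, out$kind)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, kind) in selection", call. = FALSE)
  class(out) <- c("label_sites", "data.frame")
  out
}

#' Pairwise Euclidean distances between label sites
#'
#' All unordered site pairs with their inter-site distances in Angstrom.
#'
#' @param sites a `label_sites` data.frame (from [read_sites()] or
#'   [make_dimer_fixture()])
#' @return data.frame with columns `site_a`, `site_b`, `kind_a`, `kind_b`,
#'   `r_A`; empty for fewer than two sites
#' @export
pairwise_distances <- function(sites) {
  n <- nrow(sites)
  empty <- data.frame(site_a = character(0), site_b = character(0),
                      kind_a = character(0), kind_b = character(0),
                      r_A = numeric(0))
  if (is.null(n) || n < 2) return(empty)
  idx <- utils::combn(n, 2)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  r <- sqrt(rowSums((xyz[idx[1, ], , drop = FALSE] -
                     xyz[idx[2, ], , drop = FALSE])^2))
  data.frame(site_a = sites$name[idx[1, ]], site_b = sites$name[idx[2, ]],
             kind_a = sites$kind[idx[1, ]], kind_b = sites$kind[idx[2, ]],
             r_A = r)
}

#' Is a distance measurable under given PELDOR acquisition settings?
#'
#' A dipolar coupling is considered measurable when its perpendicular
#' frequency completes at least `min_cycles` of a cycle over the dipolar
#' evolution window `n_points * dt` and does not exceed the Nyquist
#' frequency `1/(2 dt)`. The 0.4-cycle default admits the 49 and 29 A
#' label pairs of the resting-state dimer at a 148 x 8 ns acquisition and
#' rejects the > 60 A cross-dimer pairs.
#'
#' @param r distance, Angstrom (vectorised)
#' @param timing a [peldor_timing()]
#' @param min_cycles minimum fraction of a dipolar cycle in the window
#' @inheritParams spin_pair
#' @return data.frame with columns `r_A`, `nu_MHz`, `cycles`, `measurable`
#'   and a human-readable `rationale`
#' @export
is_measurable <- function(r, timing = peldor_timing(), min_cycles = 0.4,
                          g1 = G_FREE, g2 = G_FREE) {
  stopifnot(inherits(timing, "peldor_timing"))
  if (any(r <= 0)) stop("distances must be > 0", call. = FALSE)
  nu <- perpendicular_frequency(r / 10, g1, g2)
  window_us <- timing$n_points * timing$dt * 1e-3
  nyquist <- 1e3 / (2 * timing$dt)
  cycles <- nu * window_us
  ok_slow <- cycles >= min_cycles
  ok_fast <- nu <= nyquist
  rationale <- ifelse(!ok_slow,
    sprintf("only %.2f dipolar cycles in the %.3g us window (need %.2g)",
            cycles, window_us, min_cycles),
    ifelse(!ok_fast,
      sprintf("%.3g MHz exceeds the %.3g MHz Nyquist limit", nu, nyquist),
      sprintf("%.2f dipolar cycles in window, below Nyquist", cycles)))
  data.frame(r_A = r, nu_MHz = nu, cycles = cycles,
             measurable = ok_slow & ok_fast, rationale = rationale)
}

#' Reconcile measured distance assignments with structural predictions
#'
#' Greedy nearest-distance matching: each assignment is matched to at
#' most one measurable prediction within `tolerance`, taking candidate
#' pairs in order of increasing distance gap (ties broken by the
#' predictions' site names, lexically), so the result is stable under
#' input reordering. When an assignment declares the spin-pair kinds it
#' was measured between (e.g. a cobalt--nitroxide experiment), only
#' predictions connecting sites of those kinds are eligible -- a
#' label--label distance on a structure cannot explain a cobalt--label
#' coupling however close the numbers fall.
#'
#' @param assignments numeric vector of measured distances (Angstrom), or
#'   a data.frame with column `r_A` and optionally `kind_a`, `kind_b`
#' @param predictions data.frame from [pairwise_distances()], with a
#'   logical `measurable` column (e.g. merged from [is_measurable()]);
#'   rows without one are treated as measurable
#' @param tolerance maximum |measured - predicted| gap, Angstrom
#'   (default 5)
#' @return list with data.frames `matches` (`r_A`, `site_a`, `site_b`,
#'   `predicted_A`, `gap_A`), `unmatched_assignments`, and
#'   `unmatched_predictions` (with a `reason` column)
#' @export
reconcile <- function(assignments, predictions, tolerance = 5) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (is.numeric(assignments))
    assignments <- data.frame(r_A = assignments)
  if (!nrow(assignments) || is.null(assignments$r_A))
    assignments <- data.frame(r_A = numeric(0))
  if (is.null(predictions$measurable)) predictions$measurable <- TRUE
  kinds_given <- all(c("kind_a", "kind_b") %in% names(assignments))
  na <- nrow(assignments); np <- nrow(predictions)
  cand <- expand.grid(ai = seq_len(na), pj = seq_len(np))
  if (nrow(cand)) {
    cand$gap <- abs(assignments$r_A[cand$ai] - predictions$r_A[cand$pj])
    ok <- predictions$measurable[cand$pj] & cand$gap <= tolerance
    if (kinds_given) {
      ka <- assignments$kind_a[cand$ai]; kb <- assignments$kind_b[cand$ai]
      pa <- predictions$kind_a[cand$pj]; pb <- predictions$kind_b[cand$pj]
      ok <- ok & ((ka == pa & kb == pb) | (ka == pb & kb == pa))
    }
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[order(cand$gap, predictions$site_a[cand$pj],
                       predictions$site_b[cand$pj]), , drop = FALSE]
  }
  used_a <- logical(na); used_p <- logical(np)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    ai <- cand$ai[i]; pj <- cand$pj[i]
    if (used_a[ai] || used_p[pj]) next
    used_a[ai] <- used_p[pj] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      r_A = assignments$r_A[ai],
      site_a = predictions$site_a[pj], site_b = predictions$site_b[pj],
      predicted_A = predictions$r_A[pj], gap_A = cand$gap[i])
  }
  matches <- if (length(rows)) do.call(rbind, rows)
             else data.frame(r_A = numeric(0), site_a = character(0),
                             site_b = character(0), predicted_A = numeric(0),
                             gap_A = numeric(0))
  un_p <- predictions[!used_p, , drop = FALSE]
  un_p$reason <- ifelse(un_p$measurable, "no assignment within tolerance",
                        "not measurable")
  list(matches = matches,
       unmatched_assignments = assignments[!used_a, , drop = FALSE],
       unmatched_predictions = un_p)
}
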