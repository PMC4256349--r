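# Unified entry point: subcommand dispatch for shell use, plus the
# end-to-end "reproduce" driver that regenerates the package's headline
# numbers from its own simulators and fixtures. A thin Rscript wrapper
# lives at inst/cli/workbench.R.

.parse_argv <- function(argv) {
  # --key value and --flag pairs; first bare token is the subcommand
  out <- list(command = NULL, opts = list())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(argv) && !startsWith(argv[[i + 1L]], "--")) {
        out$opts[[key]] <- argv[[i + 1L]]; i <- i + 2L
      } else { out$opts[[key]] <- TRUE; i <- i + 1L }
    } else {
      if (is.null(out$command)) out$command <- a
      else stop("unexpected argument: ", a, call. = FALSE)
      i <- i + 1L
    }
  }
  out
}

.opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

.need_file <- function(path, what) {
  if (is.null(path)) stop("missing required option --", what, call. = FALSE)
  if (!file.exists(path)) stop(what, " file not found: ", path,
                               call. = FALSE)
  path
}

.write_manifest <- function(out_dir, command, opts, seed, outputs) {
  jsonlite::write_json(
    list(command = command, options = opts, seed = seed,
         package_version = as.character(utils::packageVersion("peldorkin")),
         outputs = outputs, timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

#' Recompute the package's headline numbers
#'
#' End-to-end driver over packaged logic only: the four dipolar
#' frequency-to-distance conversions (0.5, 2.1, 0.6, 0.7 MHz), the two
#' catalytic-efficiency table entries that are self-consistent at printed
#' precision, a seeded simulate-then-analyze PELDOR round trip, and the
#' open-fixture reconciliation of the measured resting-state distances.
#'
#' @param seed integer seed for the simulated round trip
#' @return a nested list (also the JSON payload written by the
#'   `reproduce` subcommand of [run_workbench()])
#' @export
reproduce_report <- function(seed = 1) {
  conv <- data.frame(nu_MHz = c(0.5, 2.1, 0.6, 0.7))
  conv$r_A <- distance_from_frequency(conv$nu_MHz, unit = "A")

  eff <- list(
    WT = efficiency_with_error(list(kcat = 2.97, Km_uM = 189))$value_1e3,
    D627A = efficiency_with_error(list(kcat = 2.89, Km_uM = 193))$value_1e3)

  trace <- simulate_peldor(
    components = data.frame(r_nm = 2.916, weight = 1),
    noise_sd = 0.02, seed = seed, collapse_theta = TRUE)
  rt <- analyze_peldor(trace, baseline_order = 0)

  open_sites <- make_dimer_fixture("open")
  pred <- pairwise_distances(open_sites)
  pred$measurable <- is_measurable(pred$r_A)$measurable
  rec <- reconcile(c(47, 29), pred)

  list(
    distance_conversions = conv,
    efficiency_1e3 = eff,
    round_trip = list(true_r_A = 29.16,
                      recovered_A = rt$assignments$r_A[1]),
    open_fixture_matches = rec$matches)
}

#' Command-line workbench dispatcher
#'
#' Subcommands (see the package vignette for the underlying science):
#' \describe{
#'   \item{`simulate`}{`--kind peldor|mm|stopped-flow|fixture --seed N
#'     --out DIR` plus kind-specific options (`--r-nm`, `--mod-depth`,
#'     `--noise-sd`; `--kcat`, `--km`, `--noise-cv`; `--kobs`;
#'     `--conformation`).}
#'   \item{`analyze-peldor`}{`--trace FILE --timing FILE [--g1 G --g2 G
#'     --baseline-order K --zero-fill N] --out DIR`.}
#'   \item{`fit-kinetics`}{`--mode mm --data FILE [--enzyme-nM X]` or
#'     `--mode expo --trace FILE [--dead-time-ms X]`, with `--out DIR`.}
#'   \item{`map-structure`}{`--pdb FILE --sites FILE(.yaml) --assignments
#'     FILE(.csv with r_A) --out DIR`.}
#'   \item{`reproduce`}{`--out DIR [--seed N]`: runs
#'     [reproduce_report()].}
#' }
#' Results are written as JSON/TSV into `--out`; a `manifest.json`
#' recording command, options, seed and package version accompanies
#' every run.
#'
#' @param argv character vector of command-line arguments
#' @return exit status, invisibly (0 on success); stops with a usage
#'   error on unknown commands or unreadable inputs
#' @export
run_workbench <- function(argv) {
  parsed <- .parse_argv(argv)
  cmd <- parsed$command
  opts <- parsed$opts
  if (is.null(cmd))
    stop("usage: workbench <simulate|analyze-peldor|fit-kinetics|",
         "map-structure|reproduce> [--options]", call. = FALSE)
  out_dir <- opts$out %||% "."
  seed <- as.integer(.opt_num(opts, "seed", 1))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)

  if (cmd == "simulate") {
    kind <- opts$kind %||% "peldor"
    if (kind == "peldor") {
      tr <- simulate_peldor(
        components = data.frame(r_nm = .opt_num(opts, "r-nm", 4.703),
                                weight = 1),
        mod_depth = .opt_num(opts, "mod-depth", 0.3),
        noise_sd = .opt_num(opts, "noise-sd", 0), seed = seed)
      outputs <- write_peldor_trace(tr, file.path(out_dir, "trace.csv"),
                                    file.path(out_dir, "timing.json"))
    } else if (kind == "mm") {
      ds <- simulate_mm(kcat = .opt_num(opts, "kcat", 2.97),
                        Km = .opt_num(opts, "km", 189),
                        noise_cv = .opt_num(opts, "noise-cv", 0.05),
                        seed = seed)[[1]]
      f <- file.path(out_dir, "mm.csv")
      utils::write.csv(data.frame(s_uM = ds$s, v = ds$v), f,
                       row.names = FALSE)
      outputs <- f
    } else if (kind == "stopped-flow") {
      tr <- simulate_stopped_flow(kobs = .opt_num(opts, "kobs", 877),
                                  noise_sd = .opt_num(opts, "noise-sd", 0),
                                  seed = seed)
      f <- file.path(out_dir, "stopped_flow.csv")
      utils::write.csv(data.frame(time_s = tr$time, A528 = tr$A), f,
                       row.names = FALSE)
      outputs <- f
    } else if (kind == "fixture") {
      f <- file.path(out_dir, paste0("dimer_",
                                     opts$conformation %||% "open",
                                     "_synthetic.pdb"))
      make_dimer_fixture(opts$conformation %||% "open", file = f)
      outputs <- f
    } else stop("unknown simulate kind: ", kind, call. = FALSE)

  } else if (cmd == "analyze-peldor") {
    tr <- read_peldor_trace(.need_file(opts$trace, "trace"),
                            .need_file(opts$timing, "timing"))
    res <- analyze_peldor(tr, g1 = .opt_num(opts, "g1", G_FREE),
                          g2 = .opt_num(opts, "g2", G_FREE),
                          baseline_order = .opt_num(opts,
                                                    "baseline-order", 2),
                          zero_fill_to = .opt_num(opts, "zero-fill", 1024))
    f1 <- file.path(out_dir, "assignments.tsv")
    utils::write.table(res$assignments, f1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    f2 <- file.path(out_dir, "analysis.json")
    jsonlite::write_json(list(assignments = res$assignments,
                              params = res$params), f2,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(f1, f2)

  } else if (cmd == "fit-kinetics") {
    mode <- opts$mode %||% "mm"
    if (mode == "mm") {
      df <- utils::read.csv(.need_file(opts$data, "data"))
      cfg <- assay_config(enzyme_conc = .opt_num(opts, "enzyme-nM",
                                                 100) * 1e-9)
      fit <- fit_mm(mm_dataset(df$s_uM, df$v, config = cfg))
      f <- file.path(out_dir, "mm_fit.json")
      jsonlite::write_json(list(kcat = fit$kcat, kcat_se = fit$kcat_se,
                                Km_uM = fit$Km_uM, Km_se = fit$Km_se,
                                efficiency_1e3 = fit$efficiency_1e3,
                                efficiency_se_1e3 = fit$efficiency_se / 1e3),
                           f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      outputs <- f
    } else if (mode == "expo") {
      df <- utils::read.csv(.need_file(opts$trace, "trace"))
      fit <- fit_exponential(df[[1]], df[[2]],
                             dead_time = .opt_num(opts, "dead-time-ms",
                                                  1) * 1e-3)
      f <- file.path(out_dir, "exp_fit.json")
      jsonlite::write_json(list(kobs = fit$kobs, kobs_se = fit$kobs_se,
                                amplitude = fit$amplitude, a0 = fit$a0,
                                low_confidence = fit$low_confidence),
                           f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      outputs <- f
    } else stop("unknown fit-kinetics mode: ", mode, call. = FALSE)

  } else if (cmd == "map-structure") {
    sel <- yaml::read_yaml(.need_file(opts$sites, "sites"))
    sites <- read_sites(.need_file(opts$pdb, "pdb"),
                        do.call(rbind, lapply(sel$sites, as.data.frame)))
    pred <- pairwise_distances(sites)
    pred$measurable <- is_measurable(pred$r_A)$measurable
    f1 <- file.path(out_dir, "predictions.tsv")
    utils::write.table(pred, f1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    outputs <- f1
    if (!is.null(opts$assignments)) {
      meas <- utils::read.csv(.need_file(opts$assignments, "assignments"))
      rec <- reconcile(meas, pred,
                       tolerance = .opt_num(opts, "tolerance", 5))
      f2 <- file.path(out_dir, "reconciliation.json")
      jsonlite::write_json(rec, f2, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      outputs <- c(outputs, f2)
    }

  } else if (cmd == "reproduce") {
    rep <- reproduce_report(seed = seed)
    f <- file.path(out_dir, "reproduce.json")
    jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <- f

  } else stop("unknown command: ", cmd, call. = FALSE)

  .write_manifest(out_dir, cmd, opts, seed, outputs)
  invisible(0L)
}
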