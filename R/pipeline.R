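#' Read / write a pipeline run configuration (JSON)
#'
#' The run configuration binds the pipeline stages: alignment path, outgroup,
#' optional enumeration constraint, substitution-model settings, RELL settings
#' (`n_bootstrap`, `seed` — mandatory), calibration (point + CI in years),
#' clade queries, rate-grid settings and the output directory. Configs
#' round-trip: `read_config(write_config(cfg, p))` is identical.
#'
#' @param config named list.
#' @param path JSON file path.
#' @return the config list.
#' @export
read_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(config)
}

# FNV-1a over the canonical JSON rendering; provenance tag for output headers
config_hash <- function(config) {
  if (!is.null(config$alignment) && !is.character(config$alignment)) {
    config$alignment <- unclass(as_alignment(config$alignment))
  }
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647  # polynomial rolling hash below 2^31
  }
  sprintf("%08x", h)
}

#' Export per-site log-likelihoods as TSV
#'
#' One file per topology: columns `site` (1-based) and `log_likelihood`.
#'
#' @param fits named list of fits (names = topology ids).
#' @param dir output directory.
#' @return paths, invisibly.
#' @export
export_site_logliks <- function(fits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(fits), function(i) {
    p <- file.path(dir, sprintf("sitelik_%03d.tsv", i))
    sll <- fits[[i]]$site_log_likelihoods
    con <- file(p, "wb")
    writeLines(c(paste0("# topology_id: ", names(fits)[i]),
                 "site\tlog_likelihood",
                 sprintf("%d\t%.10g", seq_along(sll), sll)), con)
    close(con)
    p
  }, "")
  invisible(paths)
}

#' Run the full divergence-dating pipeline
#'
#' Enumerate candidate topologies, fit each by maximum likelihood, weight them
#' by bp-RELL, test the strict clock on the best topology, fit the calibration
#' density, and produce topology-averaged divergence-date distributions for
#' the queried clades. Deterministic given the seeds in the config; all
#' outputs are plain text (Newick/TSV/JSON) headed by the config hash and
#' seed.
#'
#' @param config list (or path to a JSON config) with elements:
#'   `alignment` (path, or an alignment object), `outgroup` (labels),
#'   `constraint` (optional clade constraint for enumeration),
#'   `rell` (`n_bootstrap`, `seed`), `calibration` (`point`, `ci_low`,
#'   `ci_high`, years), `clades` (named list of label vectors), `top_k`
#'   (default 10), `reoptimize_model` (per-topology model re-optimization,
#'   default TRUE), `grid` (rate-grid settings), `out_dir` (optional: write
#'   outputs there), `write_site_logliks` (default FALSE).
#' @return list: `topologies`, `fits`, `weights`, `clock_test`,
#'   `calibration`, `report` (a [date_report()]), `model`, `config`.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  need <- c("alignment", "outgroup", "rell", "calibration", "clades")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config lacks: ", paste(miss, collapse = ", "))
  if (is.null(config$rell$seed)) stop("config$rell$seed is mandatory")
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) {
    line <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(...))
    message(line)
    log <<- c(log, line)
  }
  aln <- if (is.character(config$alignment)) {
    read_alignment(config$alignment)
  } else {
    as_alignment(config$alignment)
  }
  say("alignment: %d taxa x %d sites", length(aln$taxa), aln$length)

  topologies <- enumerate_topologies(aln$taxa, config$constraint)
  say("enumerated %d topologies%s", length(topologies),
      if (is.null(config$constraint)) "" else " (constrained)")

  # model shared across topologies (fitted once on a distance topology)
  # unless per-topology re-optimization is requested
  reopt <- config$reoptimize_model %||% FALSE
  fits <- fit_topology_set(aln, topologies, reoptimize_model = reopt)
  model <- attr(fits, "model")
  say("base model: AG %.3g CT %.3g alpha %.3g", model$rate_AG,
      model$rate_CT, model$gamma_shape)
  lls <- vapply(fits, `[[`, 0, "log_likelihood")
  say("fitted %d topologies; best logL %.4f", length(fits), max(lls))

  mat <- site_loglik_matrix(fits)
  weights <- bp_rell(mat, n_bootstrap = config$rell$n_bootstrap %||% 10000L,
                     seed = config$rell$seed)
  top <- top_k_mass(weights, min(config$top_k %||% 10L, nrow(weights)))
  say("bp-RELL: top-%d mass %.3f; best weight %.3f", length(top$topology_ids),
      top$mass, max(weights$weight))

  best_id <- top$topology_ids[1]
  rooted_best <- root_with_outgroup(topologies[[best_id]], config$outgroup)
  clock_best <- fit_strict_clock(aln, rooted_best, model = model,
                                 optimize_model = reopt)
  lrt <- clock_lrt(fits[[best_id]]$log_likelihood,
                   clock_best$log_likelihood, length(aln$taxa))
  say("clock LRT: stat %.4f, df %d, p = %.4f", lrt$statistic, lrt$df,
      lrt$p_value)

  calib <- fit_skew_normal(config$calibration$point,
                           config$calibration$ci_low,
                           config$calibration$ci_high)
  report <- date_report(aln, topologies, weights, calib, config$clades,
                        outgroup = config$outgroup,
                        top_k = config$top_k %||% 10L,
                        model = if (reopt) NULL else model,
                        grid = config$grid %||% list())
  for (i in seq_len(nrow(report$summary))) {
    s <- report$summary[i, ]
    say("%s: best %.1f ky (%.1f-%.1f), averaged %.1f ky (%.1f-%.1f)",
        s$clade, s$best_date / 1e3, s$best_lo / 1e3, s$best_hi / 1e3,
        s$avg_date / 1e3, s$avg_lo / 1e3, s$avg_hi / 1e3)
  }
  res <- list(topologies = topologies, fits = fits, weights = weights,
              clock_test = lrt, calibration = calib, report = report,
              model = model, config = config, log = log)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

# minimal neighbor-joining starting topology from JC distances
base_nj_topology <- function(aln) {
  aln <- as_alignment(aln)
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$taxa
  d <- ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "JC69",
                     pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 0.5)
  ape::unroot(ape::nj(d))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(res$config)
  seed <- res$config$rell$seed
  hdr <- c(sprintf("config_hash: %s", hash), sprintf("seed: %d", seed))
  write_topologies(res$topologies, file.path(out_dir, "topologies.nwk"))
  write_weights(res$weights, file.path(out_dir, "weights.tsv"), hdr)
  # per-topology fit summary
  con <- file(file.path(out_dir, "fits.tsv"), "wb")
  writeLines(c(paste0("# ", hdr), "topology_id\tlog_likelihood"), con)
  writeLines(sprintf("%s\t%.10f", names(res$fits),
                     vapply(res$fits, `[[`, 0, "log_likelihood")), con)
  close(con)
  s <- res$report$summary
  con <- file(file.path(out_dir, "dates.tsv"), "wb")
  writeLines(c(paste0("# ", hdr),
               "clade\tbest_date\tbest_lo\tbest_hi\tavg_date\tavg_lo\tavg_hi"),
             con)
  writeLines(sprintf("%s\t%.1f\t%.1f\t%.1f\t%.1f\t%.1f\t%.1f", s$clade,
                     s$best_date, s$best_lo, s$best_hi, s$avg_date, s$avg_lo,
                     s$avg_hi), con)
  close(con)
  jsonlite::write_json(
    list(config_hash = hash, seed = seed,
         clock_test = res$clock_test,
         top_weights = utils::head(
           res$weights[order(-res$weights$weight), ], 10),
         dates = s),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  # full averaged distributions, one row per (clade, age, mass)
  con <- file(file.path(out_dir, "distributions.tsv"), "wb")
  writeLines(c(paste0("# ", hdr), "clade\tage\tmass"), con)
  for (nm in names(res$report$distributions)) {
    d <- res$report$distributions[[nm]]$averaged
    writeLines(sprintf("%s\t%.6g\t%.10g", nm, d$x, d$p), con)
  }
  close(con)
  writeLines(c(paste0("# ", hdr), res$log), file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
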