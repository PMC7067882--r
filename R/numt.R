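#' Sliding-window mismatch profile of two aligned sequences
#'
#' Screens a query mtDNA sequence against a trusted reference for numt-like
#' segments: per window, the mismatch rate over "called" positions (both
#' sequences an unambiguous A/C/G/T). Gaps, Ns and ambiguity codes count
#' neither as called nor as mismatches. Windows with fewer than `min_called`
#' called positions are masked (rate `NA`), mirroring the usual "values not
#' shown if < 200 bp called" rule. Coordinates are 0-based half-open.
#'
#' @param query,reference equal-length aligned sequences (strings, or
#'   anything [as_alignment()] accepts for a pair).
#' @param window window size in aligned positions (default 1000).
#' @param step offset between window starts (default 100; `step = window`
#'   tiles the sequence).
#' @param min_called minimum called positions for a window to be reported
#'   (default 200).
#' @return data.frame with `start`, `end`, `called`, `mismatches`, `rate`
#'   (NA when masked) and `masked`.
#' @export
mismatch_scan <- function(query, reference, window = 1000L, step = 100L,
                          min_called = 200L) {
  q <- toupper(as.character(query))
  r <- toupper(as.character(reference))
  if (nchar(q) != nchar(r)) stop("query and reference lengths differ")
  L <- nchar(q)
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) stop("need window >= step >= 1")
  if (window > L) stop("window longer than the alignment")
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  called <- qc %in% DNA_BASES & rc %in% DNA_BASES
  mm <- called & qc != rc
  ccum <- c(0, cumsum(called))
  mcum <- c(0, cumsum(mm))
  starts <- seq.int(0L, L - window, by = step)
  ends <- starts + window
  ncall <- ccum[ends + 1] - ccum[starts + 1]
  nmm <- mcum[ends + 1] - mcum[starts + 1]
  masked <- ncall < min_called
  rate <- ifelse(masked, NA_real_, nmm / pmax(ncall, 1L))
  data.frame(start = starts, end = ends, called = ncall, mismatches = nmm,
             rate = rate, masked = masked)
}

#' Flag numt-candidate intervals from a mismatch profile
#'
#' Marks windows whose mismatch rate exceeds `fold_threshold` times the
#' background rate and merges overlapping or adjacent flagged windows into
#' half-open intervals.
#'
#' @param profile output of [mismatch_scan()].
#' @param background_rate expected mismatch rate of clean sequence.
#' @param fold_threshold flag windows with
#'   `rate > fold_threshold * background_rate` (default 4).
#' @return data.frame with `start`, `end` (0-based half-open), possibly empty.
#' @export
flag_numt_candidates <- function(profile, background_rate,
                                 fold_threshold = 4) {
  if (!nrow(profile)) stop("empty profile")
  hit <- !profile$masked & !is.na(profile$rate) &
    profile$rate > fold_threshold * background_rate
  if (!any(hit)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  s <- profile$start[hit]; e <- profile$end[hit]
  ord <- order(s)
  s <- s[ord]; e <- e[ord]
  out_s <- s[1]; out_e <- e[1]
  res <- list()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= out_e) {
      out_e <- max(out_e, e[i])
    } else {
      res[[length(res) + 1]] <- c(out_s, out_e)
      out_s <- s[i]; out_e <- e[i]
    }
  }
  res[[length(res) + 1]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Plot a mismatch profile
#'
#' Mismatch rate against window midpoint, with masked windows omitted and
#' flagged intervals (if given) shaded.
#'
#' @param profile output of [mismatch_scan()].
#' @param flags optional intervals from [flag_numt_candidates()].
#' @param ... passed to [plot()].
#' @return invisibly, the profile.
#' @export
plot_mismatch_profile <- function(profile, flags = NULL, ...) {
  mid <- (profile$start + profile$end) / 2
  plot(mid, profile$rate, type = "l", xlab = "position (bp)",
       ylab = "mismatch rate", ...)
  if (!is.null(flags) && nrow(flags)) {
    usr <- graphics::par("usr")
    graphics::rect(flags$start, usr[3], flags$end, usr[4],
                   col = grDevices::adjustcolor("firebrick", 0.2),
                   border = NA)
  }
  graphics::points(mid[profile$masked], rep(0, sum(profile$masked)),
                   pch = 4, col = "grey60")
  invisible(profile)
}

#' Write flagged intervals as BED
#'
#' @param intervals data.frame from [flag_numt_candidates()].
#' @param path output path.
#' @param name sequence/chromosome name for column 1.
#' @return `path` invisibly.
#' @export
write_bed <- function(intervals, path, name = "query") {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(intervals)) {
    writeLines(sprintf("%s\t%d\t%d", name, intervals$start, intervals$end),
               con)
  }
  invisible(path)
}
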