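#' Probe-level signal tracks
#'
#' A signal track is one mark in one condition: a set of probe intervals
#' (0-based half-open) each carrying a log2 enrichment ratio. Probes are
#' kept sorted by (chrom, start); duplicate identical intervals are
#' collapsed to their mean value with a warning. A per-chromosome
#' midpoint index is precomputed for fast region queries.
#'
#' @param probes Data frame with columns chrom, start, end, value.
#' @param mark Mark name (e.g. "MIRA", "H3K36me3").
#' @param condition Condition name (e.g. "WT", "DKO").
#' @return A `signal_track` object.
#' @export
signal_track <- function(probes, mark, condition) {
  stopifnot(nzchar(mark), nzchar(condition),
            all(c("chrom", "start", "end", "value") %in% names(probes)))
  probes <- data.frame(chrom = as.character(probes$chrom),
                       start = as.integer(probes$start),
                       end = as.integer(probes$end),
                       value = as.numeric(probes$value),
                       stringsAsFactors = FALSE)
  if (any(probes$start >= probes$end)) stop("probe with start >= end")
  if (any(!is.finite(probes$value))) stop("non-finite probe value")
  o <- order(probes$chrom, probes$start, probes$end)
  probes <- probes[o, , drop = FALSE]
  key <- paste(probes$chrom, probes$start, probes$end)
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate probe interval(s) collapsed by mean",
                    sum(duplicated(key))))
    agg <- tapply(probes$value, key, mean)
    keep <- !duplicated(key)
    probes <- probes[keep, , drop = FALSE]
    probes$value <- as.numeric(agg[paste(probes$chrom, probes$start,
                                         probes$end)])
  }
  rownames(probes) <- NULL
  probes$mid <- (probes$start + probes$end) %/% 2L
  idx <- split(seq_len(nrow(probes)), probes$chrom)
  structure(list(mark = mark, condition = condition, probes = probes,
                 index = idx),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %s / %s — %d probes on %d chromosome(s)\n",
              x$mark, x$condition, nrow(x$probes), length(x$index)))
  invisible(x)
}

#' Read a probe-level signal track
#'
#' Supported formats: `bedgraph` / `tsv4` (chrom, start, end, value;
#' track/comment lines skipped) and `wig` (fixedStep and variableStep
#' blocks, converted to interval probes). Non-numeric values abort with
#' the offending line number; unsorted input is sorted silently.
#'
#' @param path File path.
#' @param format "bedgraph", "tsv4" or "wig".
#' @param mark,condition Track identity.
#' @return A [signal_track].
#' @export
read_signal_track <- function(path, format = c("bedgraph", "tsv4", "wig"),
                              mark, condition) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("signal file not found: %s", path))
  lines <- readLines(path)
  probes <- if (format == "wig") {
    parse_wig(lines, path)
  } else {
    parse_bedgraph(lines, path)
  }
  signal_track(probes, mark, condition)
}

parse_bedgraph <- function(lines, path) {
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop(sprintf("%s line %d: expected 4 columns, found %d",
                 path, lineno[which(nf < 4L)[1]], nf[which(nf < 4L)[1]]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  for (col in list(list(start, "start"), list(end, "end"),
                   list(value, "value"))) {
    if (anyNA(col[[1]])) {
      stop(sprintf("%s line %d: non-numeric %s field",
                   path, lineno[which(is.na(col[[1]]))[1]], col[[2]]))
    }
  }
  data.frame(chrom = m[, 1], start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

parse_wig <- function(lines, path) {
  out <- list()
  chrom <- NULL; mode <- NULL; pos <- NA_integer_
  step <- 1L; span <- 1L
  kv <- function(decl, key, default = NA) {
    m <- regmatches(decl, regexec(paste0(key, "=([^ \t]+)"), decl))[[1]]
    if (length(m) < 2) default else m[2]
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^(#|track|browser)", ln)) next
    if (grepl("^fixedStep", ln)) {
      mode <- "fixed"
      chrom <- kv(ln, "chrom")
      pos <- as.integer(kv(ln, "start")) - 1L  # WIG is 1-based
      step <- as.integer(kv(ln, "step", "1"))
      span <- as.integer(kv(ln, "span", "1"))
      if (is.na(chrom) || is.na(pos)) {
        stop(sprintf("%s line %d: malformed fixedStep declaration", path, i))
      }
      next
    }
    if (grepl("^variableStep", ln)) {
      mode <- "variable"
      chrom <- kv(ln, "chrom")
      span <- as.integer(kv(ln, "span", "1"))
      if (is.na(chrom)) {
        stop(sprintf("%s line %d: malformed variableStep declaration", path, i))
      }
      next
    }
    if (is.null(mode)) {
      stop(sprintf("%s line %d: data before step declaration", path, i))
    }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (mode == "fixed") {
      v <- suppressWarnings(as.numeric(f[1]))
      if (is.na(v)) stop(sprintf("%s line %d: non-numeric value", path, i))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = pos + span, value = v,
        stringsAsFactors = FALSE)
      pos <- pos + step
    } else {
      p <- suppressWarnings(as.integer(f[1])) - 1L
      v <- suppressWarnings(as.numeric(f[2]))
      if (is.na(p) || is.na(v)) {
        stop(sprintf("%s line %d: malformed variableStep record", path, i))
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = p, end = p + span, value = v,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop(sprintf("no data records in %s", path))
  do.call(rbind, out)
}

# Index range of probes whose midpoint lies in [start, end) on `chrom`.
# Returns integer row indices into track$probes (possibly empty).
probe_rows_in <- function(track, chrom, start, end) {
  rows <- track$index[[chrom]]
  if (is.null(rows) || end <= start) return(integer(0))
  mids <- track$probes$mid[rows]
  lo <- findInterval(start - 0.5, mids) + 1L
  hi <- findInterval(end - 0.5, mids)
  if (hi < lo) integer(0) else rows[lo:hi]
}

#' Probes assigned to a region
#'
#' Membership is by probe midpoint (floor of (start+end)/2) falling in
#' the half-open region interval; assignment is strand-agnostic. With
#' `params$probe_assign == "any_overlap"` any overlapping probe is
#' included instead.
#'
#' @param track [signal_track].
#' @param region [region].
#' @param params [analysis_params].
#' @return Data frame of assigned probes (chrom, start, end, value, mid).
#' @export
assign_probes <- function(track, region, params = analysis_params()) {
  params <- as_params(params)
  if (params$probe_assign == "midpoint") {
    rows <- probe_rows_in(track, region$chrom, region$start, region$end)
  } else {
    cand <- track$index[[region$chrom]]
    if (is.null(cand)) return(track$probes[integer(0), ])
    p <- track$probes[cand, ]
    rows <- cand[p$start < region$end & p$end > region$start]
  }
  track$probes[rows, , drop = FALSE]
}

#' Mean probe signal in a region
#'
#' Arithmetic (length-unweighted) mean of assigned probe values, or NA
#' when fewer than `min_probes` probes fall in the region. Missingness
#' is explicit: an empty region never yields 0.
#'
#' @inheritParams assign_probes
#' @param min_probes Override of `params$min_probes`.
#' @return Mean log2 ratio, or NA_real_ when undefined.
#' @export
region_mean_signal <- function(track, region, params = analysis_params(),
                               min_probes = NULL) {
  params <- as_params(params)
  if (is.null(min_probes)) min_probes <- params$min_probes
  v <- assign_probes(track, region, params)$value
  if (length(v) < min_probes) NA_real_ else mean(v)
}

#' Positive-probe coverage fraction of a region
#'
#' Fraction of assigned probes with log2 ratio strictly greater than
#' `theta_pos`. A probe exactly at the threshold is not positive. NA when
#' no probe is assigned.
#'
#' @inheritParams assign_probes
#' @return Fraction in [0, 1], or NA_real_ for an empty region.
#' @export
positive_fraction <- function(track, region, params = analysis_params()) {
  params <- as_params(params)
  v <- assign_probes(track, region, params)$value
  if (!length(v)) return(NA_real_)
  mean(v > params$theta_pos)
}

#' Write a signal track as bedGraph
#' @param track [signal_track].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_signal_track <- function(track, path) {
  data.table::fwrite(track$probes[, c("chrom", "start", "end", "value")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
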