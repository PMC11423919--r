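# Internal helpers: deterministic TSV writing, seeded RNG scopes, interval
# overlap, bedGraph export.

# Deterministic TSV writer: tab-separated, header, no quoting, "NA" for
# missing, numbers pre-formatted by the caller.
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Format a numeric column to 6 significant digits for TSV output.
fmtNum <- function(x, digits = 6L) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- formatC(signif(x[ok], digits), digits = digits, format = "g")
  out
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state. All package randomness flows through explicit seeds.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item child seed that stays inside 32-bit integer range.
childSeed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + i * 7919) %% 2147483647)
}

#' Jaccard overlap of two residue intervals
#'
#' `|intersection| / |union|` of two 1-based inclusive intervals, the
#' measure used to compare a called motif with a planted ground-truth
#' segment.
#'
#' @param a,b integer length-2 vectors `c(start, end)`.
#' @return a number in \[0, 1\].
#' @examples
#' jaccardInterval(c(28, 36), c(28, 36))   # 1
#' jaccardInterval(c(28, 36), c(33, 40))   # partial overlap
#' @export
jaccardInterval <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1] <= a[2], b[1] <= b[2])
  inter <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  uni <- (a[2] - a[1] + 1L) + (b[2] - b[1] + 1L) - inter
  inter / uni
}

#' Export a residue profile as a bedGraph track
#'
#' Converts the per-residue interaction profile to bedGraph (0-based,
#' half-open), merging runs of equal value. Undefined (zero-coverage)
#' positions are omitted, as bedGraph has no NA representation.
#'
#' @param profile a [ResidueProfile-class].
#' @param path output file.
#' @param name chromosome/sequence name for column 1 (the bait id).
#' @param trackLine write a `track type=bedGraph` header line.
#' @return invisibly, `path`.
#' @export
writeBedGraph <- function(profile, path, name = "bait", trackLine = TRUE) {
  stopifnot(is(profile, "ResidueProfile"))
  v <- profile@score
  con <- file(path, "w")
  on.exit(close(con))
  if (trackLine)
    writeLines(sprintf("track type=bedGraph name=%s", name), con)
  if (any(!is.na(v))) {
    r <- rle(ifelse(is.na(v), NA_character_, fmtNum(v)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values)
    writeLines(sprintf("%s\t%d\t%d\t%s", name, starts[keep] - 1L,
                       ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

# Timestamped logging to stderr plus an optional open connection.
logMsg <- function(..., con = NULL) {
  line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ", ...)
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}
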