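# The tab-separated result file format, its reader (used by the join
# tool), and text histogram summaries.
#
# Layout: "#"-prefixed header lines carrying the tool version and
# configuration, then one row per repeat:
#   chrom  start  end  unit  geneLabel  forwardChanges  reverseChanges [score]
# geneLabel is "geneName:category" or "."; change lists are
# comma-joined signed integers, empty when no read of that strand gave
# a prediction.  Coordinates are 0-based half-open.

result_header <- function(config, multipliers = region_multipliers) {
  c(sprintf("#tandemcn %s", as.character(utils::packageVersion("tandemcn"))),
    sprintf("#mismap_max=%g", config$mismap_max),
    sprintf("#far_floor=%d near_floor=%d", config$far_floor,
            config$near_floor),
    sprintf("#min_unit=%d", config$min_unit),
    sprintf("#multipliers=%s",
            paste(names(multipliers), multipliers, sep = ":",
                  collapse = ",")))
}

fmt_changes <- function(x) vapply(x, function(v) paste(v, collapse = ","),
                                  character(1L))

#' Write genotyping results to a TSV stream
#'
#' Rows are ordered by priority rank when a ranking is supplied (the
#' usual case when gene annotations were given), else by (chrom, start).
#' Repeats without any prediction are omitted unless \code{all = TRUE}.
#'
#' @param results a \code{tg_results} data frame.
#' @param path output file path or connection.
#' @param ranked optional \code{tg_priority} from [tg_prioritize()]; its
#'   order and scores are used.
#' @param all include repeats with no predictions (empty change fields).
#' @param config configuration echoed into the header.
#' @export
write_results <- function(results, path, ranked = NULL, all = FALSE,
                          config = tg_config()) {
  cfg <- attr(results, "config")
  if (!is.null(cfg)) config <- cfg
  if (!is.null(ranked)) {
    df <- ranked
  } else {
    counts <- lengths(results$forwardChanges) + lengths(results$reverseChanges)
    df <- results[all | counts > 0L, , drop = FALSE]
    df <- df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
    df$score <- NULL
  }
  gene <- if (!is.null(df$geneName))
    ifelse(nzchar(df$geneName) | df$category != "intergenic",
           paste0(df$geneName, ":", df$category), ".")
  else rep(".", nrow(df))
  cols <- list(df$chrom, df$start, df$end, df$unit, gene,
               fmt_changes(df$forwardChanges), fmt_changes(df$reverseChanges))
  if (!is.null(df$score)) cols <- c(cols, list(format(df$score, digits = 6,
                                                      trim = TRUE,
                                                      scientific = FALSE)))
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(result_header(config), body), path)
}

parse_changes <- function(s, line) {
  if (!nzchar(s)) return(integer(0L))
  v <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))
  if (anyNA(v)) stop_line(line, "unparseable change list: ", s)
  v
}

#' Read a result file written by [write_results()]
#'
#' @param path file path or connection.
#' @return a \code{tg_results} data frame (with context columns when the
#'   file carried gene labels).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  n <- length(lines)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  unit <- character(n); geneName <- character(n); category <- character(n)
  fwd <- vector("list", n); rev <- vector("list", n); score <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    # strsplit drops trailing empty fields (empty change lists)
    if (length(f) == 6L && grepl("\t$", lines[k])) f <- c(f, "")
    if (length(f) < 7L)
      stop_line(lineno[k], "result row has ", length(f),
                " columns, expected >= 7")
    chrom[k] <- f[1L]
    start[k] <- as.integer(f[2L]); end[k] <- as.integer(f[3L])
    unit[k] <- f[4L]
    if (identical(f[5L], ".")) {
      geneName[k] <- ""; category[k] <- "intergenic"
    } else {
      gl <- strsplit(f[5L], ":", fixed = TRUE)[[1L]]
      geneName[k] <- gl[1L]
      category[k] <- if (length(gl) > 1L) gl[2L] else "intergenic"
    }
    fwd[[k]] <- parse_changes(f[6L], lineno[k])
    rev[[k]] <- parse_changes(f[7L], lineno[k])
    if (length(f) >= 8L) score[k] <- as.numeric(f[8L])
  }
  df <- data.frame(chrom = chrom, start = start, end = end, unit = unit,
                   geneName = geneName, category = category,
                   stringsAsFactors = FALSE)
  df$u <- nchar(df$unit)
  df$name <- rep_len("", n)
  df$multiplier <- unname(region_multipliers[df$category])
  df$forwardChanges <- fwd
  df$reverseChanges <- rev
  if (any(!is.na(score))) df$score <- score
  class(df) <- c("tg_results", "data.frame")
  df
}

#' Integer-binned histogram of copy changes, per strand
#'
#' @param forward,reverse per-strand copy-change vectors.
#' @param binwidth bin width in copies (default 1).
#' @return list of two data frames (forward, reverse) with columns
#'   center and count; counts sum to the number of predictions.
#' @export
tg_histogram <- function(forward, reverse = integer(0L), binwidth = 1L) {
  one <- function(x) {
    if (length(x) == 0L)
      return(data.frame(center = numeric(0L), count = integer(0L)))
    b <- round(x / binwidth) * binwidth
    t <- table(b)
    data.frame(center = as.numeric(names(t)), count = as.integer(t))
  }
  list(forward = one(forward), reverse = one(reverse))
}
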