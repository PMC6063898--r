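## Genomic intervals and gene models.
##
## Intervals are plain data.frames in 0-based half-open coordinates
## (chrom, start, end, name, score, strand), the BED convention.  On disk
## they are BED3/BED6; rtracklayer handles the 1-based/0-based conversion.

#' Construct a set of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Validation enforces `0 <= start < end` and
#' non-empty chromosome names.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based start positions.
#' @param end Integer vector of end positions (exclusive).
#' @param name Optional interval labels (recycled).
#' @param score Optional numeric scores (recycled, default 0).
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (recycled, default `"."`).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = 0, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
}

validate_intervals <- function(df) {
  required <- c("chrom", "start", "end")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing interval columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    if (any(is.na(df$chrom) | !nzchar(df$chrom)))
      stop("chromosome names must be non-empty", call. = FALSE)
    bad <- which(!(df$start >= 0 & df$start < df$end))
    if (length(bad))
      stop(sprintf("invalid interval at row %d: need 0 <= start < end (got [%s, %s))",
                   bad[1], df$start[bad[1]], df$end[bad[1]]), call. = FALSE)
  }
  if (is.null(df$name)) df$name <- NA_character_
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "."
  df[, c("chrom", "start", "end", "name", "score", "strand"),
     drop = FALSE]
}

intervals_to_granges <- function(df) {
  strand <- ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
  if (!all(is.na(df$name))) gr$name <- df$name
  gr$score <- df$score
  gr
}

granges_to_intervals <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  sc <- if (!is.null(gr$score)) as.numeric(gr$score) else 0
  genomic_intervals(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    name = nm, score = sc, strand = strand)
}

#' Read and write BED interval files
#'
#' Files are parsed as 0-based half-open BED3/BED6; `write_bed()` followed
#' by `read_bed()` is an identity on the interval set.
#'
#' @param path File path.
#' @param intervals Interval data.frame (see [genomic_intervals()]).
#' @return `read_bed()` returns an interval data.frame; `write_bed()`
#'   returns `path` invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  granges_to_intervals(gr)
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  rtracklayer::export(intervals_to_granges(intervals), path, format = "BED")
  invisible(path)
}

#' Read a gene annotation table
#'
#' Reads a tab-separated annotation with columns `gene_id`, `chrom`,
#' `start`, `end`, `strand` (0-based half-open gene bodies) and derives
#' the TSS and TTS from the strand: on `+` the TSS is `start` and the TTS
#' is `end - 1`; on `-` the TSS is `end - 1` and the TTS is `start`.
#'
#' @param path Path to the TSV annotation.
#' @return A data.frame of gene models with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`, `tts`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  gene_models(df$gene_id, df$chrom, df$start, df$end, df$strand)
}

#' Construct gene models
#'
#' @param gene_id Gene identifiers (unique).
#' @param chrom,start,end Gene body in 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Gene-model data.frame with derived `tss` and `tts` columns.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id))
    stop("gene_id values must be unique", call. = FALSE)
  if (!all(strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'", call. = FALSE)
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid gene body at row ", bad[1], call. = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$tts <- ifelse(df$strand == "+", df$end - 1, df$start)
  df
}

#' @rdname read_annotation
#' @param genes Gene-model data.frame.
#' @export
write_annotation <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# TRUE for intervals in `x` that overlap any interval in `y`
# (half-open overlap on the same chromosome).
overlaps_any <- function(x, y) {
  if (!nrow(y)) return(rep(FALSE, nrow(x)))
  out <- logical(nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yi <- y[y$chrom == ch, , drop = FALSE]
    if (!nrow(yi)) next
    for (i in xi) {
      out[i] <- any(x$start[i] < yi$end & yi$start < x$end[i])
    }
  }
  out
}

interval_id <- function(df) {
  sprintf("%s:%d-%d", df$chrom, as.integer(df$start), as.integer(df$end))
}
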