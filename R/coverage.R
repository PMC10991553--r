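#' Per-base strand-specific coverage
#'
#' The pipeline's central currency: for every chromosome, two per-base
#' numeric vectors (`fwd`, `rev`). Raw coverage is non-negative; ratio and
#' normalized tracks reuse the same container and may contain `NA` for
#' masked positions (e.g. zero coverage in the uninduced denominator).
#'
#' @param data Named list (one element per chromosome) of
#'   `list(fwd = <numeric>, rev = <numeric>)`.
#' @param chrom_sizes Named lengths (or a [genome_spec()]).
#' @param kind Free-text tag (`"coverage"`, `"ratio"`, `"normalized"`).
#' @return An object of class `strand_coverage`.
#' @export
strand_coverage <- function(data, chrom_sizes, kind = "coverage") {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (!setequal(names(data), names(chrom_sizes)))
    stop("coverage chromosomes do not match chrom_sizes")
  data <- data[names(chrom_sizes)]
  for (chr in names(data)) {
    d <- data[[chr]]
    if (!all(c("fwd", "rev") %in% names(d)))
      stop("each chromosome needs 'fwd' and 'rev' vectors")
    if (length(d$fwd) != chrom_sizes[[chr]] || length(d$rev) != chrom_sizes[[chr]])
      stop(sprintf("vector length != chromosome length on %s", chr))
    if (kind == "coverage" && (any(d$fwd < 0, na.rm = TRUE) || any(d$rev < 0, na.rm = TRUE)))
      stop("coverage values must be non-negative")
  }
  structure(list(chrom_sizes = chrom_sizes, data = data, kind = kind),
            class = "strand_coverage")
}

#' @export
print.strand_coverage <- function(x, ...) {
  cat(sprintf("strand_coverage (%s): %d chromosome(s), %s bp\n",
              x$kind, length(x$chrom_sizes),
              format(sum(x$chrom_sizes), big.mark = ",")))
  invisible(x)
}

# Flat constructor for a genome-wide constant track.
flat_coverage <- function(chrom_sizes, value = 0, kind = "coverage") {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  data <- lapply(chrom_sizes, function(L)
    list(fwd = rep(value, L), rev = rep(value, L)))
  strand_coverage(data, chrom_sizes, kind)
}

# Strand-summed per-base coverage for one chromosome.
summed_strands <- function(cov, chr) cov$data[[chr]]$fwd + cov$data[[chr]]$rev

same_genome <- function(a, b) {
  identical(names(a$chrom_sizes), names(b$chrom_sizes)) &&
    all(a$chrom_sizes == b$chrom_sizes)
}

#' Build strand-specific coverage from reads
#'
#' Piles up strand-tagged read intervals into per-base coverage, the step
#' implied between mapped reads and the strand-specific tracks. Reads
#' scoring below `min_score` (e.g. a mapping-quality stand-in) are
#' dropped.
#'
#' @param reads A read set: data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`), optional `score`.
#' @param genome Chromosome sizes or [genome_spec()].
#' @param min_score Optional minimum score; rows below it are dropped.
#' @return A `strand_coverage` of raw counts.
#' @examples
#' reads <- data.frame(chrom = "c", start = 10, end = 15, strand = "+")
#' cov <- coverage_from_reads(reads, c(c = 100))
#' sum(cov$data$c$fwd) == 5
#' @export
coverage_from_reads <- function(reads, genome, min_score = NULL) {
  chrom_sizes <- as_chrom_sizes(genome)
  reads <- validate_reads(reads, chrom_sizes)
  if (!is.null(min_score) && "score" %in% names(reads))
    reads <- reads[reads$score >= min_score, , drop = FALSE]
  data <- lapply(names(chrom_sizes), function(chr) {
    L <- chrom_sizes[[chr]]
    per_strand <- function(sym) {
      sel <- reads$chrom == chr & reads$strand == sym
      if (!any(sel)) return(numeric(L))
      ir <- IRanges::IRanges(start = reads$start[sel] + 1L, end = reads$end[sel])
      as.numeric(IRanges::coverage(ir, width = L))
    }
    list(fwd = per_strand("+"), rev = per_strand("-"))
  })
  names(data) <- names(chrom_sizes)
  strand_coverage(data, chrom_sizes)
}

validate_reads <- function(reads, chrom_sizes) {
  reads <- as.data.frame(reads)
  req <- c("chrom", "start", "end", "strand")
  if (!all(req %in% names(reads)))
    stop("read set needs columns: ", paste(req, collapse = ", "))
  if (nrow(reads) == 0L) return(reads)
  if (!all(reads$strand %in% c("+", "-")))
    stop("read strand must be '+' or '-'")
  if (!all(reads$chrom %in% names(chrom_sizes)))
    stop("read on unknown chromosome: ",
         paste(unique(setdiff(reads$chrom, names(chrom_sizes))), collapse = ", "))
  bad <- which(reads$start < 0 | reads$end <= reads$start |
                 reads$end > chrom_sizes[reads$chrom])
  if (length(bad))
    stop(sprintf("read out of bounds (first offending record: %s:%d-%d)",
                 reads$chrom[bad[1]], reads$start[bad[1]], reads$end[bad[1]]))
  reads
}

#' Ratio of a coverage track to the uninduced (t0) sample
#'
#' Divides each time point's coverage position-by-position by the
#' coverage of the uninduced sample, per strand. Positions where the
#' denominator is zero are masked (`NA`), never infinite.
#'
#' @param cov_t `strand_coverage` after induction.
#' @param cov_t0 `strand_coverage` of the uninduced sample (same genome).
#' @return A `strand_coverage` of kind `"ratio"` with `NA` at masked
#'   positions.
#' @export
t0_ratio <- function(cov_t, cov_t0) {
  stopifnot(inherits(cov_t, "strand_coverage"), inherits(cov_t0, "strand_coverage"))
  if (!same_genome(cov_t, cov_t0)) stop("genome mismatch between samples")
  data <- lapply(names(cov_t$chrom_sizes), function(chr) {
    one <- function(s) {
      num <- cov_t$data[[chr]][[s]]
      den <- cov_t0$data[[chr]][[s]]
      r <- num / den
      r[den == 0] <- NA_real_
      r
    }
    list(fwd = one("fwd"), rev = one("rev"))
  })
  names(data) <- names(cov_t$chrom_sizes)
  strand_coverage(data, cov_t$chrom_sizes, kind = "ratio")
}
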