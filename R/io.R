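#' Read a chrom.sizes file
#'
#' Two whitespace-delimited columns: chromosome name and length (bp).
#' Duplicate names, non-numeric lengths and malformed lines are rejected
#' with the offending line number.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("empty chrom.sizes file: ", path)
  nm <- character(length(keep)); len <- numeric(length(keep))
  for (i in seq_along(keep)) {
    fields <- strsplit(trimws(lines[keep[i]]), "\\s+")[[1]]
    if (length(fields) != 2L || is.na(suppressWarnings(as.numeric(fields[2]))))
      stop(sprintf("malformed chrom.sizes line %d: '%s'", keep[i], lines[keep[i]]))
    nm[i] <- fields[1]; len[i] <- as.numeric(fields[2])
  }
  if (anyDuplicated(nm))
    stop("duplicate chromosome name: ", nm[anyDuplicated(nm)])
  as_chrom_sizes(stats::setNames(len, nm))
}

#' Write a chrom.sizes file
#' @param chrom_sizes Named lengths or [genome_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  cs <- as_chrom_sizes(chrom_sizes)
  writeLines(sprintf("%s\t%d", names(cs), as.integer(cs)), path)
  invisible(path)
}

# Run-length encode a per-base vector into bedGraph rows (zero runs and
# masked positions are omitted; absent intervals read back as 0).
vector_to_bedgraph <- function(v, chrom) {
  v[is.na(v)] <- 0
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep], value = r$values[keep])
}

#' Write a strand-specific coverage track as a bedGraph pair
#'
#' One bedGraph per strand (suffixes `.fwd.bedGraph`, `.rev.bedGraph`),
#' 4 columns, 0-based half-open, run-length merged, zero intervals
#' omitted. A `#` header records tool version, seed and a config
#' fingerprint for provenance.
#'
#' @param cov A `strand_coverage`.
#' @param prefix Output path prefix.
#' @param seed,config Optional provenance recorded in the header.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_bedgraph_pair <- function(cov, prefix, seed = NULL, config = NULL) {
  stopifnot(inherits(cov, "strand_coverage"))
  paths <- c(fwd = paste0(prefix, ".fwd.bedGraph"),
             rev = paste0(prefix, ".rev.bedGraph"))
  for (s in c("fwd", "rev")) {
    rows <- do.call(rbind, lapply(names(cov$chrom_sizes), function(chr)
      vector_to_bedgraph(cov$data[[chr]][[s]], chr)))
    con <- file(paths[[s]], "w")
    writeLines(provenance_header(seed, config,
                                 sprintf("# strand=%s", s)), con)
    if (!is.null(rows) && nrow(rows))
      writeLines(sprintf("%s\t%d\t%d\t%s", rows$chrom,
                         as.integer(rows$start), as.integer(rows$end),
                         format(rows$value, scientific = FALSE, trim = TRUE,
                                digits = 15)), con)
    close(con)
  }
  invisible(paths)
}

parse_bedgraph <- function(path, chrom_sizes) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|track|browser|$)", lines))
  vecs <- lapply(chrom_sizes, function(L) numeric(L))
  if (length(keep) == 0L) return(vecs)
  sp <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(sp)
  if (any(nf != 4L))
    stop(sprintf("malformed bedGraph line %d in %s", keep[which(nf != 4L)[1]], path))
  m <- matrix(unlist(sp), ncol = 4, byrow = TRUE)
  chrom <- m[, 1]
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  value <- as.numeric(m[, 4])
  if (any(is.na(start) | is.na(end) | is.na(value)))
    stop("non-numeric coordinates or value in ", path)
  if (!all(chrom %in% names(chrom_sizes)))
    stop("bedGraph interval on unknown chromosome in ", path)
  if (any(start < 0 | end <= start | end > chrom_sizes[chrom]))
    stop("bedGraph interval beyond chromosome bounds in ", path)
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    o <- order(start[sel])
    s <- start[sel][o]; e <- end[sel][o]
    if (any(s[-1] < e[-length(e)]))
      stop(sprintf("overlapping bedGraph intervals on %s in %s", chr, path))
    v <- vecs[[chr]]
    for (i in seq_along(s)) v[(s[i] + 1):e[i]] <- value[sel][o][i]
    vecs[[chr]] <- v
  }
  vecs
}

#' Read a strand-specific bedGraph pair into coverage
#'
#' Inverse of [write_bedgraph_pair()]: dense per-base vectors, with
#' unspecified intervals set to 0. Overlapping intervals within a file
#' and coordinates beyond the genome are rejected.
#'
#' @param fwd_path,rev_path Paths to the forward/reverse bedGraphs.
#' @param genome Chromosome sizes or [genome_spec()].
#' @return A `strand_coverage`.
#' @export
read_bedgraph_pair <- function(fwd_path, rev_path, genome) {
  cs <- as_chrom_sizes(genome)
  fwd <- parse_bedgraph(fwd_path, cs)
  rev <- parse_bedgraph(rev_path, cs)
  data <- lapply(names(cs), function(chr) list(fwd = fwd[[chr]], rev = rev[[chr]]))
  names(data) <- names(cs)
  strand_coverage(data, cs)
}

#' Read strand-tagged reads from a BED6 file
#'
#' Columns: chrom, start, end, name, score, strand (0-based half-open).
#' Rows scoring below `min_score` are dropped (the score column stands
#' in for mapping quality, since alignment itself is out of scope) and
#' the number dropped is reported via `message()`.
#'
#' @param path BED6 file path.
#' @param genome Chromosome sizes or [genome_spec()].
#' @param min_score Optional score threshold (kept if `score >= min_score`).
#' @return A read data.frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`).
#' @export
read_bed_reads <- function(path, genome, min_score = NULL) {
  cs <- as_chrom_sizes(genome)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|track|browser|$)", lines))
  if (length(keep) == 0L) stop("no records in BED file: ", path)
  sp <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(sp)
  if (any(nf < 6L))
    stop(sprintf("malformed BED6 line %d (%d column(s)) in %s",
                 keep[which(nf < 6L)[1]], nf[which(nf < 6L)[1]], path))
  m <- do.call(rbind, lapply(sp, `[`, 1:6))
  reads <- data.frame(chrom = m[, 1],
                      start = as.numeric(m[, 2]), end = as.numeric(m[, 3]),
                      name = m[, 4], score = as.numeric(m[, 5]),
                      strand = m[, 6])
  if (!all(reads$strand %in% c("+", "-"))) {
    bad <- which(!reads$strand %in% c("+", "-"))[1]
    stop(sprintf("invalid strand '%s' at BED line %d", reads$strand[bad], keep[bad]))
  }
  validate_reads(reads, cs)
  if (!is.null(min_score)) {
    dropped <- sum(reads$score < min_score)
    if (dropped > 0)
      message(sprintf("read_bed_reads: dropped %d/%d reads with score < %s",
                      dropped, nrow(reads), format(min_score)))
    reads <- reads[reads$score >= min_score, , drop = FALSE]
  }
  rownames(reads) <- NULL
  reads
}

#' Write a data.frame as a provenance-stamped TSV
#'
#' Column-named, tab-separated, preceded by `#` header lines carrying
#' tool version, seed and config fingerprint, so re-running with the
#' same configuration is bit-identical for deterministic stages.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param seed,config Optional provenance for the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  writeLines(provenance_header(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a provenance-stamped TSV written by [write_tsv()]
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a peak set as BED3
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @param seed,config Optional provenance for the header.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  writeLines(provenance_header(seed, config), con)
  if (nrow(peaks))
    utils::write.table(
      data.frame(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
                 format(peaks$end, scientific = FALSE, trim = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}
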