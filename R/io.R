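#' Read a CGmap-style per-cytosine methylation count file
#'
#' Reads the 8-column tab-separated per-cytosine format produced by
#' bisulfite methylation callers: chromosome, Watson-strand nucleotide
#' (`C` for a plus-strand cytosine, `G` for a minus-strand one), 1-based
#' position, context class (`CG`/`CHG`/`CHH`), two-letter dinucleotide
#' context, methylation level, methylated read count and total read count.
#' The level column is advisory: it is cross-checked against
#' `meth / total` (a discrepancy above 0.01 raises a warning) and the
#' recomputed value is what downstream code uses.
#'
#' @param path Path to a headerless tab-separated file.
#' @return A tibble with columns `chrom`, `pos`, `strand`, `context`
#'   (`"CpG"` or `"CpH"`), `meth`, `total`.
#' @export
read_cgmap <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "base", "pos", "context_class", "dinucleotide",
                  "level", "meth", "total"),
    col_types = readr::cols(
      chrom = readr::col_character(), base = readr::col_character(),
      pos = readr::col_double(), context_class = readr::col_character(),
      dinucleotide = readr::col_character(), level = readr::col_double(),
      meth = readr::col_double(), total = readr::col_double()
    ),
    progress = FALSE
  )
  normalize_cgmap(x, source = path)
}

# validate and normalise an in-memory CGmap-style table
normalize_cgmap <- function(x, source = "cgmap input") {
  need <- c("chrom", "base", "pos", "context_class", "meth", "total")
  if (!all(need %in% names(x))) {
    rlang::abort(paste0(source, ": missing required CGmap columns"))
  }
  bad <- which(!is.finite(x$meth) | !is.finite(x$total) | x$meth < 0 |
                 x$total < 0 | x$meth > x$total)
  if (length(bad)) {
    rlang::abort(sprintf("%s: malformed counts at line %d (meth=%s total=%s)",
                         source, bad[1], x$meth[bad[1]], x$total[bad[1]]))
  }
  if (!all(x$base %in% c("C", "G"))) {
    rlang::abort(paste0(source, ": nucleotide column must be C or G"))
  }
  if (anyDuplicated(paste(x$chrom, x$pos))) {
    rlang::abort(paste0(source, ": duplicate site in one sample"))
  }
  if ("level" %in% names(x)) {
    ok <- x$total == 0 | abs(x$level - x$meth / x$total) <= 0.01
    if (!all(ok)) {
      rlang::warn(sprintf("%s: %d rows where the level column disagrees with meth/total by > 0.01; recomputed values used",
                          source, sum(!ok)))
    }
  }
  tibble::tibble(
    chrom = x$chrom,
    pos = as.integer(x$pos),
    strand = ifelse(x$base == "C", "+", "-"),
    context = ifelse(x$context_class == "CG", "CpG", "CpH"),
    meth = as.integer(x$meth),
    total = as.integer(x$total)
  )
}

#' Write a CGmap-style table
#'
#' @param x Tibble with columns `chrom`, `base`, `pos`, `context_class`,
#'   `dinucleotide`, `level`, `meth`, `total` (as produced by
#'   [simulate_counts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(x, path) {
  readr::write_tsv(
    x[, c("chrom", "base", "pos", "context_class", "dinucleotide",
          "level", "meth", "total")],
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path Path to a 3-6 column BED file (0-based half-open).
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", comment.char = "#")
  names(x)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  k <- ncol(x) - 3L
  if (k > 0) names(x)[4:(3 + min(k, 3L))] <- extra[seq_len(min(k, 3L))]
  out <- tibble::as_tibble(x[, seq_len(min(ncol(x), 6L))])
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  if ("score" %in% names(out)) out$score <- suppressWarnings(as.numeric(out$score))
  check_intervals(out, path)
  out
}

#' Write intervals as BED
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  # BED columns are positional: keep the longest present prefix
  ordered <- c("chrom", "start", "end", "name", "score", "strand")
  present <- c(ordered %in% names(x), FALSE)
  keep <- ordered[seq_len(match(FALSE, present) - 1L)]
  df <- as.data.frame(x[, keep])
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED12 or a 6-column gene table
#'
#' BED12 files carry exon structure in blockSizes/blockStarts. The plain
#' 6-column alternative has columns `gene_id`, `chrom`, `strand`, `start`,
#' `end`, `exons`, the latter a comma-separated list of 0-based half-open
#' `start-end` pairs.
#'
#' @param path Path to the gene file.
#' @return Gene-model tibble: `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open gene body) and `exons`, a list-column of interval
#'   tibbles.
#' @export
read_gene_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE, colClasses = "character")
  if (ncol(raw) == 12) {
    genes <- tibble::tibble(
      gene_id = raw[[4]], chrom = raw[[1]], strand = raw[[6]],
      start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]])
    )
    sizes <- strsplit(raw[[11]], ",")
    starts <- strsplit(raw[[12]], ",")
    genes$exons <- purrr::pmap(list(sizes, starts, genes$start), function(sz, st, gs) {
      sz <- as.numeric(sz[nzchar(sz)]); st <- as.numeric(st[nzchar(st)])
      tibble::tibble(start = gs + st, end = gs + st + sz)
    })
  } else if (ncol(raw) == 6) {
    genes <- tibble::tibble(
      gene_id = raw[[1]], chrom = raw[[2]], strand = raw[[3]],
      start = as.numeric(raw[[4]]), end = as.numeric(raw[[5]])
    )
    genes$exons <- purrr::map(raw[[6]], function(s) {
      parts <- strsplit(strsplit(s, ",")[[1]], "-")
      tibble::tibble(start = as.numeric(purrr::map_chr(parts, 1)),
                     end = as.numeric(purrr::map_chr(parts, 2)))
    })
  } else {
    rlang::abort(paste0(path, ": expected 12 (BED12) or 6 columns"))
  }
  check_genes(genes)
}

check_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "exons")
  if (!all(need %in% names(genes))) {
    rlang::abort("gene models need columns gene_id, chrom, strand, start, end, exons")
  }
  if (!all(genes$strand %in% c("+", "-"))) rlang::abort("gene strand must be + or -")
  ok <- purrr::pmap_lgl(list(genes$exons, genes$start, genes$end), function(ex, s, e) {
    nrow(ex) > 0 && all(ex$start >= s) && all(ex$end <= e) && all(ex$end > ex$start)
  })
  if (!all(ok)) rlang::abort("gene exons must lie within the gene body")
  genes
}

#' Write gene models as BED12
#'
#' @param genes Gene-model tibble (see [read_gene_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed12 <- function(genes, path) {
  check_genes(genes)
  rows <- purrr::pmap_chr(
    list(genes$chrom, genes$start, genes$end, genes$gene_id, genes$strand, genes$exons),
    function(ch, s, e, id, str, ex) {
      ex <- dplyr::arrange(ex, .data$start)
      paste(ch, format(s, scientific = FALSE), format(e, scientific = FALSE), id, 0, str,
            format(s, scientific = FALSE), format(e, scientific = FALSE), "0", nrow(ex),
            paste0(paste(format(ex$end - ex$start, scientific = FALSE, trim = TRUE), collapse = ","), ","),
            paste0(paste(format(ex$start - s, scientific = FALSE, trim = TRUE), collapse = ","), ","),
            sep = "\t")
    })
  writeLines(rows, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
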