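#' Read a TE insertion table
#'
#' Tab-separated with a header naming at least
#' `chrom, start, end, family, te_type, strain, confidence`. Coordinates are
#' 0-based half-open. Calls below the confidence threshold (a coverage
#' ratio; strong calls have ratio >= 3) are dropped.
#'
#' @param path TSV path.
#' @param min_confidence minimum coverage ratio to retain a call (default 3).
#' @param assembly optional [genome_assembly()]; when given, coordinates are
#'   validated against it.
#' @return data.frame of TE insertions with an `id` column.
#' @export
read_te_table <- function(path, min_confidence = 3, assembly = NULL) {
  te <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse TE table ", path, ": ",
                             conditionMessage(e)))
  need <- c("chrom", "start", "end", "family", "te_type", "strain", "confidence")
  miss <- setdiff(need, names(te))
  if (length(miss))
    stop("TE table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("start", "end", "confidence")) {
    v <- suppressWarnings(as.numeric(te[[col]]))
    bad <- which(is.na(v) & !is.na(te[[col]]))
    if (length(bad))
      stop("malformed TE table row(s) (line ", bad[1] + 1, "): non-numeric ",
           col)
    te[[col]] <- v
  }
  if (any(te$start >= te$end)) stop("TE rows with start >= end")
  if (any(te$family == "")) stop("TE rows with empty family")
  if (any(te$confidence < 0)) stop("negative confidence values")
  if (!is.null(assembly))
    validate_coords(assembly, te$chrom, te$start, te$end, "TE insertion")
  te <- te[te$confidence >= min_confidence, , drop = FALSE]
  if (!"id" %in% names(te))
    te$id <- if (nrow(te)) sprintf("te%04d", seq_len(nrow(te))) else character(0)
  rownames(te) <- NULL
  te
}

#' Read gene models from BED or GFF3
#'
#' GFF3 input (1-based closed) is converted to the package's 0-based
#' half-open convention on read; gene spans come from `gene` features and
#' exon intervals from `exon` features grouped by `Parent`/`ID`. BED input
#' uses the span as a single exon.
#'
#' @param path `.bed`, `.gff`, or `.gff3` file.
#' @param assembly optional [genome_assembly()] for coordinate validation.
#' @return data.frame with `id, chrom, start, end, strand` and a list column
#'   `exons` of two-column matrices (start, end).
#' @export
read_genes <- function(path, assembly = NULL) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr)
  df$start <- df$start - 1  # to 0-based half-open
  if (fmt == "bed") {
    genes <- data.frame(id = if (!is.null(df$name)) df$name else
                          sprintf("gene%04d", seq_len(nrow(df))),
                        chrom = as.character(df$seqnames),
                        start = df$start, end = df$end,
                        strand = as.character(df$strand),
                        stringsAsFactors = FALSE)
    genes$exons <- lapply(seq_len(nrow(genes)), function(i)
      cbind(start = genes$start[i], end = genes$end[i]))
  } else {
    g <- df[df$type == "gene", , drop = FALSE]
    ex <- df[df$type == "exon", , drop = FALSE]
    genes <- data.frame(id = as.character(g$ID),
                        chrom = as.character(g$seqnames),
                        start = g$start, end = g$end,
                        strand = as.character(g$strand),
                        stringsAsFactors = FALSE)
    parent <- if (nrow(ex)) as.character(unlist(ex$Parent)) else character(0)
    genes$exons <- lapply(genes$id, function(id) {
      e <- ex[parent == id, , drop = FALSE]
      if (nrow(e) == 0) return(cbind(start = genes$start[genes$id == id],
                                     end = genes$end[genes$id == id]))
      cbind(start = e$start, end = e$end)
    })
  }
  bad <- vapply(seq_len(nrow(genes)), function(i) {
    e <- genes$exons[[i]]
    any(e[, 1] < genes$start[i]) || any(e[, 2] > genes$end[i])
  }, TRUE)
  if (any(bad)) stop("exons outside gene span for: ",
                     paste(genes$id[bad], collapse = ", "))
  if (!is.null(assembly))
    validate_coords(assembly, genes$chrom, genes$start, genes$end, "gene")
  genes
}

#' Write a data frame as TSV with stable formatting
#'
#' Plain `write.table` wrapper used by the pipeline so repeated runs with
#' the same seed produce byte-identical outputs.
#' @param df data.frame (list columns are dropped).
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
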