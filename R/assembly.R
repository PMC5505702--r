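#' Genome assembly with euchromatin bounds
#'
#' Minimal container for the coordinate system all analyses run on:
#' chromosome names, lengths, and the analyzable euchromatin span of each
#' chromosome. All coordinates in the package are 0-based, half-open
#' (BED/bedGraph convention); an interval `[a, b)` has length `b - a`.
#'
#' @param chrom_names character vector of chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths (bp), same
#'   length and order as `chrom_names`.
#' @param euchromatin_bounds optional data.frame with columns
#'   `chrom`, `start`, `end` giving the euchromatic span per chromosome
#'   (0-based half-open). Defaults to the whole chromosome.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(chrom_names, chrom_lengths, euchromatin_bounds = NULL) {
  stopifnot(length(chrom_names) == length(chrom_lengths),
            !anyDuplicated(chrom_names), all(chrom_lengths > 0))
  chrom_lengths <- as.numeric(chrom_lengths)
  names(chrom_lengths) <- chrom_names
  if (is.null(euchromatin_bounds)) {
    euchromatin_bounds <- data.frame(chrom = chrom_names, start = 0,
                                     end = chrom_lengths)
  }
  eb <- euchromatin_bounds
  stopifnot(all(c("chrom", "start", "end") %in% names(eb)))
  if (!all(eb$chrom %in% chrom_names))
    stop("euchromatin bounds refer to unknown chromosome(s): ",
         paste(setdiff(eb$chrom, chrom_names), collapse = ", "))
  bad <- !(eb$start >= 0 & eb$start < eb$end &
             eb$end <= chrom_lengths[eb$chrom])
  if (any(bad))
    stop("invalid euchromatin bounds for: ", paste(eb$chrom[bad], collapse = ", "))
  structure(list(chrom_names = chrom_names, chrom_lengths = chrom_lengths,
                 euchromatin_bounds = eb),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Euchromatin span of one chromosome
#' @param assembly a `genome_assembly`.
#' @param chrom chromosome name.
#' @return numeric `c(start, end)` (0-based half-open).
#' @export
euchromatin_span <- function(assembly, chrom) {
  eb <- assembly$euchromatin_bounds
  i <- match(chrom, eb$chrom)
  if (is.na(i)) stop("no euchromatin bounds for chromosome ", chrom)
  c(eb$start[i], eb$end[i])
}

# validate that features lie on named chromosomes within their lengths
validate_coords <- function(assembly, chrom, start, end, what = "feature") {
  unknown <- !(chrom %in% assembly$chrom_names)
  if (any(unknown))
    stop(what, " on unknown chromosome(s): ",
         paste(unique(chrom[unknown]), collapse = ", "))
  len <- assembly$chrom_lengths[chrom]
  bad <- start < 0 | end > len | start >= end
  if (any(bad))
    stop(what, " with invalid coordinates at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  invisible(TRUE)
}
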