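#' Read an aligned FASTA file
#'
#' Reads a multiple-sequence alignment of cpDNA sequences (e.g. concatenated
#' intergenic spacers) from FASTA. All records must have equal length;
#' symbols are uppercased and restricted to the IUPAC nucleotide alphabet
#' plus gap (`A C G T N -`; other IUPAC ambiguity codes are accepted and
#' treated like `N` downstream).
#'
#' @param path Path to a FASTA file.
#' @return A `cp_alignment` object: list with `ids` (character), `seqs`
#'   (named character vector of equal-length uppercase strings) and `k`
#'   (alignment length in bp).
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA input: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  new_cp_alignment(ids, seqs)
}

new_cp_alignment <- function(ids, seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- ids[lens != stats::median(lens)][1L]
    stop("alignment is ragged: record '", bad, "' has length ",
         nchar(seqs[bad]), ", expected ", stats::median(lens))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  allowed <- c("A", "C", "G", "T", "N", "-",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  chars <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0L) {
    pos <- regexpr(bad[1L], seqs, fixed = TRUE)
    hit <- which(pos > 0L)[1L]
    stop("non-IUPAC symbol '", bad[1L], "' in record '", ids[hit],
         "' at position ", pos[hit])
  }
  structure(list(ids = ids, seqs = seqs, k = unname(lens[1L])),
            class = "cp_alignment")
}

#' Construct an alignment from in-memory sequences
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return A `cp_alignment`.
#' @export
cp_alignment <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("ind", seq_along(seqs))
  new_cp_alignment(names(seqs), toupper(seqs))
}

#' @export
print.cp_alignment <- function(x, ...) {
  cat("cpDNA alignment:", length(x$ids), "sequences x", x$k, "bp\n")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param aln A `cp_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  out <- character(2L * length(aln$ids))
  out[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  out[c(FALSE, TRUE)] <- unname(aln$seqs)
  writeLines(out, path)
  invisible(path)
}

#' Read a population map
#'
#' Tab-separated table assigning each sequenced individual to a population
#' and each population to a region, with collection coordinates in decimal
#' degrees. Expected header: `individual`, `population`, `region`, `lat`,
#' `lon` and optionally `alt`.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with one row per individual.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  pm <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_population_map(pm)
}

validate_population_map <- function(pm) {
  need <- c("individual", "population", "region", "lat", "lon")
  miss <- setdiff(need, names(pm))
  if (length(miss) > 0L) {
    stop("population map lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(pm$individual)) {
    stop("individual listed twice in population map: ",
         pm$individual[duplicated(pm$individual)][1L])
  }
  if (any(abs(pm$lat) > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]: ",
         pm$lat[which(abs(pm$lat) > 90)[1L]])
  }
  if (any(abs(pm$lon) > 180, na.rm = TRUE)) {
    stop("longitude out of range [-180, 180]: ",
         pm$lon[which(abs(pm$lon) > 180)[1L]])
  }
  reg <- unique(pm[, c("population", "region")])
  if (anyDuplicated(reg$population)) {
    stop("population assigned to more than one region: ",
         reg$population[duplicated(reg$population)][1L])
  }
  pm
}
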