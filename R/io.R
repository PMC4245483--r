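#' Read plastome sequences from FASTA
#'
#' Reads a (multi-)FASTA file of complete plastome sequences into a tidy
#' table, one row per record. Lowercase bases are normalised to uppercase;
#' only the alphabet {A,C,G,T,N} is accepted.
#'
#' @param path path to a FASTA file.
#' @param circular logical flag recorded on each record; plastomes are
#'   circular molecules but input FASTA is assumed already linearised.
#' @return a tibble with columns `id`, `sequence`, `length`, `circular`.
#' @export
read_plastomes <- function(path, circular = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort("FASTA source contains no records", class = "plastocmp_empty_fasta")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "plastocmp_duplicate_ids")
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("illegal characters in record(s): ",
                 paste(ids[bad], collapse = ", ")),
          class = "plastocmp_illegal_characters")
  }
  tibble(id = ids, sequence = unname(seqs),
         length = unname(nchar(seqs)), circular = circular)
}

#' Write plastome sequences to FASTA
#'
#' @param plastomes tibble with `id` and `sequence` columns.
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_plastomes <- function(plastomes, path, width = 70L) {
  check_plastomes(plastomes)
  set <- Biostrings::DNAStringSet(setNames(plastomes$sequence, plastomes$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Reads the constrained GFF3 subset this package writes: one row per exon
#' with types `CDS`, `tRNA` or `rRNA` and attributes `ID` (gene copy
#' identifier), `Name` (gene symbol), `exon` (1-based transcription-order
#' rank) and `copy` (`single` or `IR-duplicated`). Rows of other types
#' (`gene`, `region`, ...) are ignored.
#'
#' @param path path to a GFF3 file.
#' @return a feature tibble with columns `gene_id`, `gene`, `category`,
#'   `strand`, `start`, `end`, `exon`, `copy`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(gene_id = character(), gene = character(),
                  category = character(), strand = character(),
                  start = integer(), end = integer(), exon = integer(),
                  copy = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(parts) == 9L
  if (!all(ncol_ok)) abort("malformed GFF3: expected 9 tab-separated columns")
  m <- do.call(rbind, parts)
  type <- m[, 3]
  keep <- type %in% c("CDS", "tRNA", "rRNA")
  m <- m[keep, , drop = FALSE]
  attr_field <- function(attrs, key) {
    val <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", attrs)
    ifelse(grepl(paste0("(^|;)", key, "="), attrs), val, NA_character_)
  }
  attrs <- m[, 9]
  category <- c(CDS = "protein_coding", tRNA = "tRNA",
                rRNA = "rRNA")[m[, 3]]
  ex <- attr_field(attrs, "exon")
  tibble(
    gene_id = attr_field(attrs, "ID"),
    gene = attr_field(attrs, "Name"),
    category = unname(category),
    strand = m[, 7],
    start = as.integer(m[, 4]),
    end = as.integer(m[, 5]),
    exon = ifelse(is.na(ex), 1L, as.integer(ex)),
    copy = dplyr::coalesce(attr_field(attrs, "copy"), "single")
  )
}

#' Write gene annotation to GFF3
#'
#' @param features feature tibble (see [read_annotation()]).
#' @param path output file path.
#' @param seqid sequence identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(features, path, seqid = "plastome") {
  type <- c(protein_coding = "CDS", tRNA = "tRNA", rRNA = "rRNA")
  lines <- c("##gff-version 3",
             sprintf("%s\tplastocmp\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;exon=%d;copy=%s",
                     seqid, type[features$category], features$start,
                     features$end, features$strand, features$gene_id,
                     features$gene, features$exon, features$copy))
  writeLines(lines, path)
  invisible(path)
}

check_features <- function(features) {
  need <- c("gene_id", "gene", "category", "strand", "start", "end",
            "exon", "copy")
  if (!is.data.frame(features) || !all(need %in% names(features))) {
    abort("`features` must be a feature tibble; see read_annotation()")
  }
  bad <- !features$category %in% c("protein_coding", "tRNA", "rRNA")
  if (any(bad)) abort("unknown feature category")
  invisible(features)
}
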