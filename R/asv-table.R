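#' Construct and validate an ASV count table
#'
#' An ASV table is an integer matrix of read counts with ASVs in rows and
#' samples in columns. Row names are ASV identifiers and column names are
#' sample identifiers; both must be unique and all counts non-negative.
#'
#' @param counts Numeric matrix of non-negative integer counts
#'   (ASVs x samples).
#' @param asv_ids Optional character vector of ASV identifiers; defaults to
#'   `rownames(counts)`.
#' @param sample_ids Optional character vector of sample identifiers;
#'   defaults to `colnames(counts)`.
#' @return The validated count matrix with dimnames set.
#' @export
asv_table <- function(counts, asv_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(asv_ids) || is.null(sample_ids))
    stop("ASV and sample identifiers are required")
  if (length(asv_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("identifier lengths do not match the count matrix dimensions")
  rownames(counts) <- as.character(asv_ids)
  colnames(counts) <- as.character(sample_ids)
  validate_asv_table(counts)
}

#' Validate ASV-table invariants
#'
#' Checks that a count matrix has unique ASV and sample identifiers,
#' numeric non-negative integer counts, and no missing values.
#'
#' @param counts Matrix to validate.
#' @return The matrix, invisibly unchanged, with counts in integer storage.
#' @export
validate_asv_table <- function(counts) {
  if (!is.matrix(counts)) stop("ASV table must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("ASV table must carry ASV row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ASV identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  counts
}

#' Read an ASV count table from TSV or BIOM
#'
#' The TSV dialect is ASVs in rows: the first column holds ASV identifiers
#' and the header row holds sample identifiers. BIOM input requires the
#' \pkg{biomformat} package.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` or `"biom"`.
#' @return A validated ASV count matrix (see [asv_table()]).
#' @export
read_asv_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "",
                            quote = "", stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("ASV table TSV needs an ID column and >= 1 sample")
    ids <- as.character(df[[1L]])
    counts <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(counts)) stop("non-numeric counts in ", path)
    asv_table(counts, asv_ids = ids, sample_ids = colnames(df)[-1L])
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    asv_table(m)
  }
}

#' Write an ASV count table to TSV or BIOM
#'
#' @param counts Validated ASV count matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"biom"`.
#' @param id_column Name of the leading identifier column in TSV output.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(counts, path, format = c("tsv", "biom"),
                            id_column = "asv_id") {
  format <- match.arg(format)
  counts <- validate_asv_table(counts)
  if (format == "tsv") {
    df <- data.frame(rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- id_column
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM files requires the 'biomformat' package")
    biomformat::write_biom(biomformat::make_biom(counts), path)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `host_species`, `host_type`
#' (conifer/broadleaf), `stage` (juvenile/adult) and `replicate`.
#'
#' @param path Path to the metadata TSV.
#' @return A data frame with the required columns.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  validate_sample_metadata(md)
}

#' Validate sample metadata against an ASV table
#'
#' @param metadata Metadata data frame.
#' @param counts Optional ASV count matrix; if given, every sample column
#'   must have exactly one metadata row.
#' @return The metadata data frame.
#' @export
validate_sample_metadata <- function(metadata, counts = NULL) {
  required <- c("sample_id", "host_species", "host_type", "stage",
                "replicate")
  missing <- setdiff(required, names(metadata))
  if (length(missing))
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(metadata$host_type), c("conifer", "broadleaf"))
  if (length(bad))
    stop("host_type must be 'conifer' or 'broadleaf'; found: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(unique(metadata$stage), c("juvenile", "adult"))
  if (length(bad))
    stop("stage must be 'juvenile' or 'adult'; found: ",
         paste(bad, collapse = ", "))
  if (!is.null(counts)) {
    absent <- setdiff(colnames(counts), metadata$sample_id)
    if (length(absent))
      stop("samples without metadata: ", paste(absent, collapse = ", "))
  }
  metadata
}

#' Read a taxonomy table with guild annotations
#'
#' Expects a TSV with columns `asv_id`, `lineage` (QIIME2-style
#' "k__...;p__...;...;s__..." string) and `is_ecm` (logical: is the genus
#' annotated as ectomycorrhizal). A `genus` column is parsed from the
#' lineage when not supplied.
#'
#' @param path Path to the taxonomy TSV.
#' @return Data frame with columns asv_id, lineage, genus, is_ecm.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("asv_id", "lineage", "is_ecm")
  missing <- setdiff(required, names(tx))
  if (length(missing))
    stop("taxonomy is missing columns: ", paste(missing, collapse = ", "))
  if (!is.logical(tx$is_ecm)) tx$is_ecm <- as.logical(tx$is_ecm)
  if (is.null(tx$genus)) tx$genus <- parse_genus(tx$lineage)
  tx
}

#' Extract the genus rank from QIIME2-style lineage strings
#'
#' @param lineage Character vector of "k__;p__;...;g__Genus;s__" strings.
#' @return Character vector of genus names ("" where unassigned).
#' @export
parse_genus <- function(lineage) {
  vapply(strsplit(lineage, ";", fixed = TRUE), function(ranks) {
    ranks <- trimws(ranks)
    g <- ranks[startsWith(ranks, "g__")]
    if (length(g)) sub("^g__", "", g[1L]) else ""
  }, character(1L))
}
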