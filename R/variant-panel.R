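# Consequence classes that qualify a variant as a structural alteration.
# Synonymous and "other" never qualify.
QUALIFYING_CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice")

# Map annotation-tool vocabulary (Sequence Ontology style) onto the closed
# consequence set.
map_consequence <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("other", length(x))
  out[x %in% c("missense", "missense_variant")] <- "missense"
  out[x %in% c("nonsense", "stop_gained")] <- "nonsense"
  out[x %in% c("frameshift", "frameshift_variant")] <- "frameshift"
  out[grepl("^splice", x)] <- "splice"
  out
}

#' Load a gene panel file
#'
#' One HGNC symbol per line; `#` starts a comment; symbols are
#' whitespace-stripped, upper-cased and de-duplicated. No alias resolution
#' is attempted (no external database access).
#'
#' @param path Panel file, or a character vector of symbols.
#' @param name Panel name (defaults to the file name).
#' @return A `gene_panel`: list with `name` and `genes` (sorted unique
#'   upper-case symbols).
#' @export
load_panel <- function(path, name = NULL) {
  if (length(path) == 1L && file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    if (is.null(name)) name <- basename(path)
  } else {
    lines <- path
    if (is.null(name)) name <- "panel"
  }
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- unique(genes[nzchar(genes)])
  if (!length(genes))
    stop("empty-panel: no gene symbols found", call. = FALSE)
  structure(list(name = name, genes = sort(genes)), class = "gene_panel")
}

#' Parse an annotated somatic variant table
#'
#' Reads either a simplified MAF-like TSV (columns `specimen_id`, `gene`,
#' `genomic_change`, `protein_change`, `consequence`, and optionally
#' `cosmic_id`, `lof_class`) or an annotated VCF whose ANN/CSQ INFO field
#' carries gene, consequence and protein change (requires the vcfR
#' package). Annotation-vocabulary consequences are mapped onto the closed
#' set \{missense, nonsense, frameshift, splice, other\}; unparseable
#' protein changes are recorded as `""`, never dropped. Genomic coordinates
#' are stored verbatim (1-based, VCF convention) and never re-normalised.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param specimen_id For VCF input without a sample column: the specimen
#'   the records belong to (defaults to the file name stem).
#' @return data.frame of variant records with columns `specimen_id`,
#'   `gene`, `genomic_change`, `protein_change`, `consequence`,
#'   `cosmic_id`, `lof_class` (defaults to `"unknown"`).
#' @export
parse_variants <- function(path, format = c("tsv", "vcf"),
                           specimen_id = NULL) {
  format <- match.arg(format)
  if (format == "vcf") return(parse_variants_vcf(path, specimen_id))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L && ncol(df) <= 1L) return(empty_variants())
  req <- c("specimen_id", "gene", "genomic_change", "protein_change",
           "consequence")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("format error: variant TSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$cosmic_id)) df$cosmic_id <- rep("", nrow(df))
  if (is.null(df$lof_class)) df$lof_class <- rep("unknown", nrow(df))
  df$lof_class[!nzchar(df$lof_class)] <- "unknown"
  df$protein_change[is.na(df$protein_change)] <- ""
  df$consequence <- map_consequence(df$consequence)
  as_variant_df(df)
}

empty_variants <- function() {
  data.frame(specimen_id = character(), gene = character(),
             genomic_change = character(), protein_change = character(),
             consequence = character(), cosmic_id = character(),
             lof_class = character(), stringsAsFactors = FALSE)
}

as_variant_df <- function(df) {
  cols <- names(empty_variants())
  df <- df[, cols]
  df$gene <- toupper(trimws(df$gene))
  if (any(!nzchar(df$gene)))
    stop("format error: empty gene symbol in variant table", call. = FALSE)
  bad <- !df$lof_class %in% c("total", "partial", "unknown")
  if (any(bad))
    stop("format error: lof_class must be total/partial/unknown",
         call. = FALSE)
  rownames(df) <- NULL
  df
}

# VCF route: gene/consequence/protein change from the ANN (SnpEff) or CSQ
# (VEP) INFO field, first annotation block per record.
parse_variants_vcf <- function(path, specimen_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF parsing requires the vcfR package", call. = FALSE)
  if (is.null(specimen_id))
    specimen_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variants())
  info <- vcfR::getINFO(v)
  ann <- sub(".*(?:ANN|CSQ)=([^;]*).*", "\\1", info)
  ann[!grepl("(ANN|CSQ)=", info)] <- ""
  first <- vapply(strsplit(ann, ","), function(x)
    if (length(x)) x[[1]] else "", character(1))
  parts <- strsplit(first, "\\|")
  get_f <- function(p, i) if (length(p) >= i) p[[i]] else ""
  # ANN field layout: Allele|Annotation|Impact|Gene_Name|...|HGVS.c|HGVS.p
  cons <- vapply(parts, get_f, character(1), i = 2L)
  gene <- vapply(parts, get_f, character(1), i = 4L)
  prot <- vapply(parts, get_f, character(1), i = 11L)
  prot[is.na(prot)] <- ""
  keep <- nzchar(gene)
  df <- data.frame(
    specimen_id = specimen_id,
    gene = gene,
    genomic_change = paste0("g.chr", fix$CHROM, ":", fix$POS,
                            fix$REF, ">", fix$ALT),
    protein_change = prot,
    consequence = map_consequence(cons),
    cosmic_id = "",
    lof_class = "unknown",
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  as_variant_df(df)
}

#' Build the specimen x gene mutation matrix
#'
#' Restricts variants to the panel and to protein-altering consequence
#' classes (missense, nonsense, frameshift, splice), then builds a binary
#' matrix over the full cohort: cell (s, g) is 1 when specimen s carries at
#' least one qualifying variant in gene g. Specimens with no qualifying
#' variant keep an all-zero row, so Mut- status is explicit.
#'
#' @param variants Variant data.frame from [parse_variants()].
#' @param panel A [load_panel()] object (or character vector of symbols).
#' @param cohort_specimens Character vector of all specimens in the cohort;
#'   must contain every specimen appearing in `variants`.
#' @param require_cosmic Keep only variants with a non-empty `cosmic_id`
#'   (optional pathogenicity proxy; default FALSE).
#' @return A `mutation_matrix`: integer matrix, specimens as rows, panel
#'   genes with at least one qualifying variant as columns.
#' @export
build_mutation_matrix <- function(variants, panel, cohort_specimens,
                                  require_cosmic = FALSE) {
  if (!inherits(panel, "gene_panel")) panel <- load_panel(panel)
  unknown <- setdiff(unique(variants$specimen_id), cohort_specimens)
  if (length(unknown))
    stop("unknown-specimen: variant specimen(s) not in cohort: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  q <- variants[variants$consequence %in% QUALIFYING_CONSEQUENCES &
                  variants$gene %in% panel$genes, , drop = FALSE]
  if (require_cosmic) q <- q[nzchar(q$cosmic_id), , drop = FALSE]
  genes <- sort(unique(q$gene))
  m <- matrix(0L, nrow = length(cohort_specimens), ncol = length(genes),
              dimnames = list(cohort_specimens, genes))
  if (nrow(q)) m[cbind(q$specimen_id, q$gene)] <- 1L
  structure(m, class = c("mutation_matrix", class(m)))
}

#' Per-specimen mutation status
#'
#' @param matrix A [build_mutation_matrix()] result.
#' @return Named logical vector: TRUE for Mut+ specimens (at least one
#'   qualifying panel variant).
#' @export
mutation_status <- function(matrix) {
  if (ncol(matrix) == 0L)
    return(stats::setNames(rep(FALSE, nrow(matrix)), rownames(matrix)))
  rowSums(matrix) > 0L
}

#' Override loss-of-function class on matching variants
#'
#' Replaces `lof_class` on variants matching (specimen, gene, protein
#' change). Used by the reassignment analysis: specimens whose only
#' qualifying variants are partial loss-of-function can be moved out of the
#' Mut+ group. An override matching no variant raises a warning, not an
#' error.
#'
#' @param variants Variant data.frame.
#' @param overrides data.frame with columns `specimen_id`, `gene`,
#'   `protein_change`, `lof_class`.
#' @return The variant data.frame with updated `lof_class`.
#' @export
apply_lof_overrides <- function(variants, overrides) {
  if (is.null(overrides) || nrow(overrides) == 0L) return(variants)
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    hit <- variants$specimen_id == o$specimen_id &
      variants$gene == toupper(trimws(o$gene)) &
      variants$protein_change == o$protein_change
    if (!any(hit)) {
      warning("lof override matched no variant: ", o$specimen_id, " ",
              o$gene, " ", o$protein_change, call. = FALSE)
      next
    }
    variants$lof_class[hit] <- o$lof_class
  }
  variants
}

#' Read the specimen annotation table
#'
#' TSV with columns `specimen_id` and `histotype` (UPS or SS).
#'
#' @param path TSV path.
#' @return data.frame with `specimen_id`, `histotype`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("specimen_id", "histotype"), names(df))
  if (length(miss))
    stop("format error: annotation TSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$histotype), c("UPS", "SS"))
  if (length(bad))
    stop("format error: histotype must be UPS or SS, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Write a mutation matrix as TSV
#'
#' @param matrix A [build_mutation_matrix()] result.
#' @param path Destination; specimens as rows, genes as columns, 0/1 cells.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(specimen_id = rownames(matrix),
                   as.data.frame(unclass(matrix)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation matrix TSV
#'
#' @param path TSV written by [write_matrix_tsv()].
#' @return A `mutation_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$specimen_id
  structure(m, class = c("mutation_matrix", class(m)))
}
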