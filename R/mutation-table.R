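#' Build a validated mutation table
#'
#' A mutation table is a tibble with one row per somatic point mutation:
#' a `gene` column plus one column per categorical attribute (by default
#' `mutation_type` and `nucleotide_change`).  Duplicate rows are meaningful
#' and are kept: each row contributes one count to its gene's conditional
#' profiles, so a mutation recurring across samples weighs in proportion to
#' its recurrence.
#'
#' Values are whitespace-trimmed and arrow spellings inside
#' `nucleotide_change` (`"→"`, `"->"`, `">"`, with or without surrounding
#' spaces) are canonicalized to `">"`, so `"GG → GT"` and `"GG>GT"` are the
#' same category.  Categories are otherwise opaque, case-sensitive strings:
#' the distance treats them as unordered labels, so only internal
#' consistency within one dataset matters.
#'
#' @param x A data frame with a `gene` column and one column per attribute.
#' @param attributes Character vector of attribute column names.  Defaults
#'   to every column except `gene`.
#' @param lenient If `TRUE`, rows with a blank gene or attribute value are
#'   dropped with a warning instead of raising an error.
#' @return A tibble of class `ccn_mut_tbl` with columns `gene` and the
#'   attributes, all character.
#' @examples
#' tab <- mutation_table(data.frame(
#'   gene = c("FAM171B", "FAM171B", "FAM171B", "ABCA6"),
#'   mutation_type = c("Missense", "Nonsense", "Missense", "Missense"),
#'   nucleotide_change = c("AA>AC", "GG>GT", "GG>GA", "GG>GT")
#' ))
#' gene_index(tab)
#' attribute_vocabulary(tab, "mutation_type")
#' @export
mutation_table <- function(x, attributes = NULL, lenient = FALSE) {
  x <- tibble::as_tibble(x)
  if (!"gene" %in% names(x)) {
    abort_config("mutation table must have a 'gene' column")
  }
  if (is.null(attributes)) attributes <- setdiff(names(x), "gene")
  if (length(attributes) < 1) {
    abort_config("at least one attribute column is required")
  }
  if (anyDuplicated(attributes)) {
    abort_config("attribute names must be unique")
  }
  missing <- setdiff(attributes, names(x))
  if (length(missing)) {
    abort_config(paste0(
      "attribute column(s) not found: ", paste(missing, collapse = ", ")
    ))
  }
  x <- x[, c("gene", attributes)]
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::everything(), ~ stringr::str_trim(as.character(.x))
  ))
  if ("nucleotide_change" %in% attributes) {
    x$nucleotide_change <- canonicalize_arrows(x$nucleotide_change)
  }

  blank <- !stats::complete.cases(x) |
    Reduce(`|`, lapply(x, function(col) is.na(col) | col == ""))
  if (any(blank)) {
    lines <- which(blank)
    if (lenient) {
      warning(sprintf(
        "dropped %d row(s) with blank gene or attribute (rows: %s)",
        length(lines), paste(utils::head(lines, 10), collapse = ", ")
      ), call. = FALSE)
      x <- x[!blank, ]
    } else {
      abort_row(sprintf(
        "blank gene or attribute value at row %d", lines[[1]]
      ))
    }
  }
  if (nrow(x) == 0) abort_empty("mutation table has no records")

  structure(x,
    class = c("ccn_mut_tbl", class(tibble::tibble()))
  )
}

#' @export
print.ccn_mut_tbl <- function(x, ...) {
  cat(sprintf(
    "# Mutation table: %d records, %d genes, attributes: %s\n",
    nrow(x), length(gene_index(x)),
    paste(attribute_names(x), collapse = ", ")
  ))
  NextMethod()
}

#' Attribute columns of a mutation table
#'
#' @param tbl A mutation table (or any data frame with a `gene` column).
#' @return Character vector of attribute column names.
#' @export
attribute_names <- function(tbl) {
  setdiff(names(tbl), "gene")
}

#' Sorted distinct genes of a mutation table
#'
#' @param tbl A mutation table.
#' @return Sorted character vector of gene identifiers.
#' @export
gene_index <- function(tbl) {
  sort(unique(tbl$gene))
}

#' Observed category vocabulary per attribute
#'
#' @param tbl A mutation table.
#' @param attribute One attribute name, or `NULL` for all attributes.
#' @return For one attribute, a sorted character vector of its observed
#'   categories; otherwise a named list of such vectors.
#' @export
attribute_vocabulary <- function(tbl, attribute = NULL) {
  atts <- attribute_names(tbl)
  if (!is.null(attribute)) {
    if (!attribute %in% atts) {
      abort_lookup(paste0("unknown attribute: ", attribute))
    }
    return(sort(unique(tbl[[attribute]])))
  }
  stats::setNames(lapply(atts, function(a) sort(unique(tbl[[a]]))), atts)
}

# "A → G", "A -> G", "A>G" all become "A>G"; applied after trimming.
canonicalize_arrows <- function(x) {
  stringr::str_replace_all(x, "\\s*(→|->|>)\\s*", ">")
}

#' Read a mutation table from a delimited text file
#'
#' Expects a tab-separated file with a header.  `column_map` names the
#' file's columns for each role; roles other than `gene` become the
#' table's attributes under their role name, so arbitrary categorical
#' attributes beyond the default two are supported.
#'
#' @param path Path to the TSV file.
#' @param column_map Named character vector mapping roles to file column
#'   names, e.g. `c(gene = "Gene", mutation_type = "Type", ...)`.
#' @param lenient Drop blank rows with a warning instead of erroring.
#' @return A `ccn_mut_tbl` tibble; rows are kept in file order and
#'   duplicates are preserved.
#' @export
read_mutation_tsv <- function(path,
                              column_map = c(
                                gene = "gene",
                                mutation_type = "mutation_type",
                                nucleotide_change = "nucleotide_change"
                              ),
                              lenient = FALSE) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) abort_empty(paste0("no data rows in ", path))
  missing <- setdiff(unname(column_map), names(raw))
  if (length(missing)) {
    abort_config(paste0(
      "column(s) missing from ", path, ": ", paste(missing, collapse = ", ")
    ))
  }
  df <- stats::setNames(raw[, unname(column_map)], names(column_map))
  mutation_table(df,
    attributes = setdiff(names(column_map), "gene"),
    lenient = lenient
  )
}

#' Write a mutation table to TSV
#'
#' The written file round-trips through [read_mutation_tsv()]: records,
#' order and vocabularies are preserved exactly.
#'
#' @param tbl A mutation table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_tsv <- function(tbl, path) {
  readr::write_tsv(tibble::as_tibble(tbl), path, progress = FALSE)
  invisible(path)
}

#' Nucleotide-change category from reference and alternate alleles
#'
#' @param ref,alt Single uppercase bases in `A`, `C`, `G`, `T`; `ref` must
#'   differ from `alt`.  Vectorized.
#' @return `"REF>ALT"` strings; exactly 12 values are possible.
#' @examples
#' derive_nucleotide_change("A", "G") # "A>G"
#' @export
derive_nucleotide_change <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  ok <- ref %in% bases & alt %in% bases & ref != alt
  if (!all(ok)) {
    bad <- which(!ok)[[1]]
    abort_domain(sprintf(
      "not a single-nucleotide substitution: ref='%s', alt='%s'",
      ref[[bad]], alt[[bad]]
    ))
  }
  paste0(ref, ">", alt)
}

#' Default mapping from MAF Variant_Classification to mutation types
#'
#' Targets the six point-mutation classes the distance is built over:
#' Missense, Nonsense, RNA, Silent, Splice_Site, Nonstop.  Matching is
#' case-insensitive; classes absent from the map are dropped (and
#' counted) by [read_maf()].
#'
#' @return Named character vector: names are MAF classifications
#'   (lower-cased), values the target categories.
#' @export
default_variant_class_map <- function() {
  c(
    missense_mutation = "Missense",
    nonsense_mutation = "Nonsense",
    rna = "RNA",
    silent = "Silent",
    splice_site = "Splice_Site",
    nonstop_mutation = "Nonstop"
  )
}

#' Read a MAF file into a mutation table
#'
#' Reads a tab-separated Mutation Annotation Format file (comment lines
#' starting with `#` are skipped) and restricts it to single-nucleotide
#' substitutions: both alleles a single base in `A/C/G/T` and unequal,
#' or `Variant_Type == "SNP"` when that column is present.  The
#' `mutation_type` attribute comes from `Variant_Classification` through
#' `class_map`; `nucleotide_change` is `REF>ALT` via
#' [derive_nucleotide_change()].  Sample identity is ignored: mutations
#' are pooled per gene.
#'
#' @param path Path to the MAF file.
#' @param class_map Named character vector mapping (lower-cased)
#'   `Variant_Classification` values to mutation-type categories; rows
#'   whose classification is unmapped are dropped and counted.
#' @return A `ccn_mut_tbl` with attributes `mutation_type` and
#'   `nucleotide_change`, carrying a `filter_report` attribute (see
#'   [filter_report()]).
#' @export
read_maf <- function(path, class_map = default_variant_class_map()) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  raw <- readr::read_tsv(path,
    comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  required <- c(
    "Hugo_Symbol", "Variant_Classification",
    "Reference_Allele", "Tumor_Seq_Allele2"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort_config(paste0(
      "MAF column(s) missing: ", paste(missing, collapse = ", ")
    ))
  }
  rows_in <- nrow(raw)
  bases <- c("A", "C", "G", "T")
  is_snv <- raw$Reference_Allele %in% bases &
    raw$Tumor_Seq_Allele2 %in% bases &
    raw$Reference_Allele != raw$Tumor_Seq_Allele2
  if ("Variant_Type" %in% names(raw)) {
    is_snv <- is_snv & raw$Variant_Type == "SNP"
  }
  snv <- raw[is_snv, ]
  dropped_non_snv <- rows_in - nrow(snv)

  mapped <- unname(class_map[tolower(snv$Variant_Classification)])
  keep <- !is.na(mapped)
  dropped_unmapped <- sum(!keep)
  if (dropped_unmapped > 0) {
    message(sprintf(
      "read_maf: dropped %d row(s) with unmapped Variant_Classification",
      dropped_unmapped
    ))
  }
  snv <- snv[keep, ]
  if (nrow(snv) == 0) {
    abort_empty(sprintf(
      paste0(
        "no records survive MAF filters (%d rows in, ",
        "%d non-SNV dropped, %d unmapped-class dropped)"
      ),
      rows_in, dropped_non_snv, dropped_unmapped
    ))
  }
  tab <- mutation_table(tibble::tibble(
    gene = snv$Hugo_Symbol,
    mutation_type = mapped[keep],
    nucleotide_change = derive_nucleotide_change(
      snv$Reference_Allele, snv$Tumor_Seq_Allele2
    )
  ))
  attr(tab, "filter_report") <- list(
    rows_in = rows_in,
    records_out = nrow(tab),
    dropped_non_snv = dropped_non_snv,
    dropped_unmapped_class = dropped_unmapped
  )
  tab
}

#' Filter accounting for a MAF-derived table
#'
#' @param tbl A table produced by [read_maf()].
#' @return A list with `rows_in`, `records_out`, `dropped_non_snv` and
#'   `dropped_unmapped_class`; these always satisfy
#'   `records_out + dropped_non_snv + dropped_unmapped_class == rows_in`.
#' @export
filter_report <- function(tbl) {
  attr(tbl, "filter_report")
}

# --- condition helpers -------------------------------------------------

abort_config <- function(msg) {
  rlang::abort(msg, class = "ccn_config_error")
}
abort_empty <- function(msg) {
  rlang::abort(msg, class = "ccn_empty_error")
}
abort_row <- function(msg) {
  rlang::abort(msg, class = "ccn_row_error")
}
abort_domain <- function(msg) {
  rlang::abort(msg, class = "ccn_domain_error")
}
abort_lookup <- function(msg) {
  rlang::abort(msg, class = "ccn_lookup_error")
}
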