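#' Readers and writers for pipeline tables
#'
#' Every external table the pipeline touches enters through one of these
#' readers, which validate strictly and hand typed in-memory objects to the
#' downstream stages. All identifiers are opaque, case-sensitive strings;
#' only tissue labels are matched case-insensitively.
#'
#' @name io_formats
NULL

# -- strict TSV matrix parsing -------------------------------------------

# Read a TSV with an id first column and numeric body. Empty cells become NA;
# any other non-numeric cell is a hard error naming the offending cell.
read_numeric_tsv <- function(path, integer = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) {
    abort(sprintf("'%s': expected an id column plus at least one sample column", path))
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("'%s': duplicate row id '%s'", path, dup))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !(is.na(body) | body == "" | body == "NA"), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("'%s': non-numeric value '%s' at row '%s', column '%s'",
                  path, body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                  colnames(raw)[-1][bad[1, 2]]))
  }
  if (integer) {
    if (any(num < 0, na.rm = TRUE)) {
      bad <- which(num < 0, arr.ind = TRUE)
      abort(sprintf("'%s': negative count at row '%s'", path, ids[bad[1, 1]]))
    }
    if (any(abs(num - round(num)) > 1e-8, na.rm = TRUE)) {
      bad <- which(abs(num - round(num)) > 1e-8, arr.ind = TRUE)
      abort(sprintf("'%s': non-integer count at row '%s'", path, ids[bad[1, 1]]))
    }
    num <- round(num)
  }
  dimnames(num) <- list(ids, colnames(raw)[-1])
  num
}

write_matrix_tsv <- function(mat, path, id_col) {
  df <- tibble::as_tibble(mat, rownames = id_col)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# -- ExpressionBundle -----------------------------------------------------

#' Construct a paired tumor/NAT expression bundle
#'
#' Holds matched tumor and normal-adjacent-tissue (NAT) count matrices with
#' identical gene and patient orderings: column `j` of both matrices belongs
#' to the same patient.
#'
#' @param counts_tumor,counts_nat non-negative integer matrices
#'   (genes x patients) with identical dimnames.
#' @return An object of class `tfa_bundle` with elements `counts_tumor`,
#'   `counts_nat`, `gene_ids`, `patient_ids`.
#' @export
expression_bundle <- function(counts_tumor, counts_nat) {
  stopifnot(is.matrix(counts_tumor), is.matrix(counts_nat))
  if (!identical(dim(counts_tumor), dim(counts_nat))) {
    abort("tumor and NAT matrices must have identical dimensions")
  }
  if (!identical(rownames(counts_tumor), rownames(counts_nat)) ||
      !identical(colnames(counts_tumor), colnames(counts_nat))) {
    abort("tumor and NAT matrices must share gene and patient orderings")
  }
  if (is.null(rownames(counts_tumor)) || is.null(colnames(counts_tumor))) {
    abort("count matrices need gene rownames and patient colnames")
  }
  if (anyDuplicated(rownames(counts_tumor))) abort("duplicate gene ids in bundle")
  if (anyDuplicated(colnames(counts_tumor))) abort("duplicate patient ids in bundle")
  if (any(counts_tumor < 0) || any(counts_nat < 0)) abort("counts must be non-negative")
  structure(
    list(counts_tumor = counts_tumor, counts_nat = counts_nat,
         gene_ids = rownames(counts_tumor), patient_ids = colnames(counts_tumor)),
    class = "tfa_bundle"
  )
}

#' @export
print.tfa_bundle <- function(x, ...) {
  cat(sprintf("<tfa_bundle> %d genes x %d patients (tumor + NAT)\n",
              length(x$gene_ids), length(x$patient_ids)))
  invisible(x)
}

#' Read paired tumor/NAT expression matrices
#'
#' @param tumor_path,nat_path TSV count matrices: first column gene id,
#'   header row of sample ids.
#' @param pairing_path TSV with columns `patient_id`, `tumor_sample`,
#'   `nat_sample` mapping sample ids to patients.
#' @return A [expression_bundle()] with columns reordered to the pairing
#'   file's patient order. Genes present in only one file are dropped with a
#'   warning; an unpairable sample is a hard error naming the sample.
#' @export
read_expression <- function(tumor_path, nat_path, pairing_path) {
  tum <- read_numeric_tsv(tumor_path, integer = TRUE)
  nat <- read_numeric_tsv(nat_path, integer = TRUE)
  pairing <- readr::read_tsv(pairing_path, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
  need <- c("patient_id", "tumor_sample", "nat_sample")
  if (!all(need %in% names(pairing))) {
    abort(sprintf("pairing file must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(pairing$patient_id)) abort("duplicate patient_id in pairing file")

  check_cols <- function(mat, wanted, label) {
    missing <- setdiff(wanted, colnames(mat))
    if (length(missing) > 0) {
      abort(sprintf("%s matrix lacks paired sample(s): %s", label,
                    paste(missing, collapse = ", ")))
    }
    extra <- setdiff(colnames(mat), wanted)
    if (length(extra) > 0) {
      abort(sprintf("unpairable %s sample(s): %s", label, paste(extra, collapse = ", ")))
    }
  }
  check_cols(tum, pairing$tumor_sample, "tumor")
  check_cols(nat, pairing$nat_sample, "NAT")

  shared <- intersect(rownames(tum), rownames(nat))
  dropped <- setdiff(union(rownames(tum), rownames(nat)), shared)
  if (length(dropped) > 0) {
    warn(sprintf("dropping %d gene(s) present in only one matrix: %s",
                 length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  if (length(shared) == 0) abort("no genes shared between tumor and NAT matrices")

  tum <- tum[shared, pairing$tumor_sample, drop = FALSE]
  nat <- nat[shared, pairing$nat_sample, drop = FALSE]
  colnames(tum) <- colnames(nat) <- pairing$patient_id
  expression_bundle(tum, nat)
}

#' Write an expression bundle to TSV files
#'
#' @param bundle a [expression_bundle()].
#' @param tumor_path,nat_path,pairing_path output file paths.
#' @export
write_expression <- function(bundle, tumor_path, nat_path, pairing_path) {
  stopifnot(inherits(bundle, "tfa_bundle"))
  tum <- bundle$counts_tumor
  nat <- bundle$counts_nat
  colnames(tum) <- paste0(bundle$patient_ids, "_T")
  colnames(nat) <- paste0(bundle$patient_ids, "_N")
  write_matrix_tsv(tum, tumor_path, "gene_id")
  write_matrix_tsv(nat, nat_path, "gene_id")
  readr::write_tsv(tibble(patient_id = bundle$patient_ids,
                          tumor_sample = colnames(tum),
                          nat_sample = colnames(nat)),
                   pairing_path, progress = FALSE)
  invisible(bundle)
}

# -- PhosphoTable ---------------------------------------------------------

#' Normalize a phosphosite identifier
#'
#' Canonical form is `PROTEIN_RESIDUEPOS` with residue in S/T/Y
#' (e.g. `"MYH9_S1943"`). Dialects using `-` or `:` as the separator are
#' normalized; anything else is rejected.
#'
#' @param x character vector of site ids.
#' @return character vector of canonical site ids.
#' @export
normalize_site_id <- function(x) {
  out <- gsub("[-:]", "_", x)
  ok <- grepl("^.+_[STY][0-9]+$", out)
  if (!all(ok)) {
    abort(sprintf("malformed phosphosite id(s): %s",
                  paste(head(x[!ok], 5), collapse = ", ")))
  }
  out
}

site_protein <- function(site_ids) {
  sub("_[STY][0-9]+$", "", site_ids)
}

#' Construct a phosphosite fold-change table
#'
#' @param log2fc numeric matrix (sites x patients) of tumor-vs-NAT log2 fold
#'   changes; `NA` marks a site not detected in that patient.
#' @return An object of class `tfa_phospho` with `log2fc`, `site_ids`,
#'   `protein_of_site` (named character) and `complete_sites` (named logical,
#'   derived: detected in every patient).
#' @export
phospho_table <- function(log2fc) {
  stopifnot(is.matrix(log2fc), !is.null(rownames(log2fc)), !is.null(colnames(log2fc)))
  sites <- normalize_site_id(rownames(log2fc))
  if (anyDuplicated(sites)) abort("duplicate phosphosite ids")
  rownames(log2fc) <- sites
  complete <- apply(log2fc, 1, function(v) all(is.finite(v)))
  if (any(!is.finite(log2fc) & !is.na(log2fc))) abort("log2fc must be finite or NA")
  structure(
    list(log2fc = log2fc, site_ids = sites,
         protein_of_site = setNames(site_protein(sites), sites),
         complete_sites = setNames(complete, sites)),
    class = "tfa_phospho"
  )
}

#' @export
print.tfa_phospho <- function(x, ...) {
  cat(sprintf("<tfa_phospho> %d sites x %d patients (%d complete)\n",
              nrow(x$log2fc), ncol(x$log2fc), sum(x$complete_sites)))
  invisible(x)
}

#' Read a phosphosite log2 fold-change matrix
#'
#' TSV with first column site id and one column per patient; empty cells are
#' missing values (site not detected for that patient).
#'
#' @param path input TSV.
#' @return a [phospho_table()].
#' @export
read_phospho <- function(path) {
  phospho_table(read_numeric_tsv(path))
}

#' @rdname read_phospho
#' @param phospho a `tfa_phospho` object to write.
#' @export
write_phospho <- function(phospho, path) {
  stopifnot(inherits(phospho, "tfa_phospho"))
  write_matrix_tsv(phospho$log2fc, path, "site_id")
  invisible(phospho)
}

# -- SETable --------------------------------------------------------------

#' Read a super-enhancer table, filtered to one tissue
#'
#' TSV columns: `se_id`, `tissue`, `tf_ids` (semicolon-joined),
#' `gene_ids` (semicolon-joined). Only rows whose tissue matches `tissue`
#' (case-insensitive exact match) are kept.
#'
#' @param path input TSV.
#' @param tissue tissue label, e.g. `"lung"`.
#' @return A tibble of class `tfa_se_table` with list-columns `tf_ids` and
#'   `gene_ids`. An empty post-filter result is a warning, not an error.
#' @export
read_se_table <- function(path, tissue) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("se_id", "tissue", "tf_ids", "gene_ids")
  if (!all(need %in% names(raw))) {
    abort(sprintf("SE table must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(raw$se_id)) abort("duplicate se_id in SE table")
  keep <- tolower(raw$tissue) == tolower(tissue)
  if (!any(keep)) {
    warn(sprintf("no SE records for tissue '%s'", tissue))
  }
  out <- raw[keep, , drop = FALSE]
  out <- tibble(
    se_id = out$se_id, tissue = out$tissue,
    tf_ids = lapply(strsplit(out$tf_ids, ";", fixed = TRUE), unique),
    gene_ids = lapply(strsplit(out$gene_ids, ";", fixed = TRUE), unique)
  )
  if (nrow(out) > 0 &&
      (any(lengths(out$tf_ids) == 0) || any(lengths(out$gene_ids) == 0))) {
    abort("SE record with empty TF or gene set")
  }
  class(out) <- c("tfa_se_table", class(out))
  out
}

#' @rdname read_se_table
#' @param se_table an SE table to write.
#' @export
write_se_table <- function(se_table, path) {
  df <- tibble(
    se_id = se_table$se_id, tissue = se_table$tissue,
    tf_ids = map_chr(se_table$tf_ids, paste, collapse = ";"),
    gene_ids = map_chr(se_table$gene_ids, paste, collapse = ";")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(se_table)
}

# -- PathwayCollection (GMT) ---------------------------------------------

#' Read a GMT pathway collection
#'
#' Standard GMT: one pathway per line, tab-separated `name`, `description`,
#' members. The description is discarded; members are deduplicated sets.
#'
#' @param path GMT file.
#' @return named list pathway -> character vector of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  names(fields) <- map_chr(fields, 1)
  if (anyDuplicated(names(fields))) abort("duplicate pathway names in GMT")
  out <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(out) == 0)) abort("empty pathway in GMT")
  out
}

#' @rdname read_gmt
#' @param pathways named list of member sets to write.
#' @export
write_gmt <- function(pathways, path) {
  lines <- imap_chr_local(pathways, function(members, name) {
    paste(c(name, "na", members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(pathways)
}

imap_chr_local <- function(x, f) {
  vapply(seq_along(x), function(i) f(x[[i]], names(x)[i]), character(1))
}

# -- SurvivalTable --------------------------------------------------------

#' Read a patient survival table
#'
#' CSV with header `patient_id,time,event`; `time` is positive follow-up
#' time and `event` is 1 if death was observed, 0 if censored.
#'
#' @param path CSV file.
#' @return tibble with columns `patient_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", time = "d", event = "d"), progress = FALSE)
  validate_survival(df)
}

validate_survival <- function(df) {
  if (anyDuplicated(df$patient_id)) abort("duplicate patient_id in survival table")
  if (any(!is.finite(df$time)) || any(df$time <= 0)) {
    abort(sprintf("non-positive survival time for patient '%s'",
                  df$patient_id[which(!(is.finite(df$time) & df$time > 0))[1]]))
  }
  if (!all(df$event %in% c(0, 1))) {
    abort(sprintf("event must be 0/1; offending patient '%s'",
                  df$patient_id[which(!df$event %in% c(0, 1))[1]]))
  }
  as_tibble(df)
}

#' @rdname read_survival
#' @param survival_df survival tibble to write.
#' @export
write_survival <- function(survival_df, path) {
  readr::write_csv(validate_survival(survival_df), path, progress = FALSE)
  invisible(survival_df)
}

# -- KinaseSubstrateMap ---------------------------------------------------

#' Read a kinase-to-substrate-site map
#'
#' TSV with columns `kinase` and `sites` (semicolon-joined phosphosite ids in
#' the same `PROTEIN_RESIDUEPOS` dialect as the phospho table).
#'
#' @param path input TSV.
#' @return named list kinase -> character vector of site ids.
#' @export
read_ksmap <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("kinase", "sites") %in% names(df))) {
    abort("kinase-substrate map must have columns kinase, sites")
  }
  if (anyDuplicated(df$kinase)) abort("duplicate kinase in map")
  out <- lapply(strsplit(df$sites, ";", fixed = TRUE),
                function(s) normalize_site_id(unique(s)))
  names(out) <- df$kinase
  if (any(lengths(out) == 0)) abort("kinase with empty substrate set")
  out
}

#' @rdname read_ksmap
#' @param ksmap named list kinase -> sites to write.
#' @export
write_ksmap <- function(ksmap, path) {
  df <- tibble(kinase = names(ksmap),
               sites = map_chr(ksmap, paste, collapse = ";"))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(ksmap)
}

# -- regulon table IO -----------------------------------------------------

#' Read or write a regulon table
#'
#' Regulons are tibbles with one row per TF-target edge and columns
#' `tf`, `target`, `mode` (+1/-1), `r`, `p`, `support`.
#'
#' @param path TSV file.
#' @return regulon tibble.
#' @export
read_regulons <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    tf = "c", target = "c", mode = "d", r = "d", p = "d", support = "d"),
    progress = FALSE)
  if (!all(df$mode %in% c(-1, 1))) abort("regulon mode must be +1/-1")
  as_tibble(df)
}

#' @rdname read_regulons
#' @param regulons regulon tibble to write.
#' @export
write_regulons <- function(regulons, path) {
  readr::write_tsv(regulons, path, progress = FALSE)
  invisible(regulons)
}
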