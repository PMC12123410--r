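#' Genes directly targeted by a TF through super-enhancers
#'
#' The direct-target set of a TF is the union of the regulated-gene sets of
#' every super-enhancer record that lists the TF among its bound TFs. The
#' SE table is assumed to be tissue-filtered already (see
#' [read_se_table()]).
#'
#' @param se_table an SE table (tibble with list-columns `tf_ids`,
#'   `gene_ids`).
#' @param tf TF id.
#' @return character vector of direct target genes (possibly empty).
#' @export
direct_target_genes <- function(se_table, tf) {
  if (nrow(se_table) == 0) return(character(0))
  hit <- vapply(se_table$tf_ids, function(s) tf %in% s, logical(1))
  genes <- unlist(se_table$gene_ids[hit], use.names = FALSE)
  if (is.null(genes)) return(character(0))
  sort(unique(genes))
}

#' Restrict regulons to super-enhancer-supported direct targets
#'
#' Keeps, per TF, only targets that appear in that TF's direct-target set;
#' modes and edge statistics are carried through unchanged. TFs whose
#' filtered regulon is empty are reported in the summary as filtered-out,
#' not raised as errors.
#'
#' @param regulons regulon tibble from [infer_regulons()].
#' @param se_table tissue-filtered SE table.
#' @return The filtered regulon tibble, with attribute `summary`: a tibble
#'   `tf`, `n_targets_before`, `n_direct`, `status` (kept/filtered_out).
#' @export
filter_regulon <- function(regulons, se_table) {
  tfs <- unique(regulons$tf)
  direct <- setNames(lapply(tfs, function(tf) direct_target_genes(se_table, tf)),
                     tfs)
  keep <- vapply(seq_len(nrow(regulons)), function(i) {
    regulons$target[i] %in% direct[[regulons$tf[i]]]
  }, logical(1))
  out <- regulons[keep, , drop = FALSE]
  summary <- map_dfr(tfs, function(tf) {
    n_before <- sum(regulons$tf == tf)
    n_direct <- sum(out$tf == tf)
    tibble(tf = tf, n_targets_before = n_before, n_direct = n_direct,
           status = if (n_direct > 0) "kept" else "filtered_out")
  })
  attr(out, "summary") <- summary
  out
}
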