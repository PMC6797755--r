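#' Mosaic-specific differential-expression gate
#'
#' Applies the mosaic-vs-ubiquitous contrast logic: a gene responding to
#' scattered (mosaic) introduction of perturbed cells but *not* to uniform
#' (ubiquitous) perturbation reflects the presence of unfit cells rather
#' than the perturbation itself. Concretely, a gene is mosaic-specific-up
#' iff it is significant (FDR < `fdr_threshold`) with a positive log2 fold
#' change in the mosaic contrast and not significant in the ubiquitous
#' contrast; mosaic-specific-down analogously with a negative fold change;
#' genes significant in both contrasts are `shared`. Genes missing from a
#' contrast, or with missing FDR, count as not significant there.
#'
#' @param records data frame with columns `gene_id`, `contrast`
#'   (`"mosaic_vs_uninjected"` / `"ubiquitous_vs_uninjected"`),
#'   `log2_fold_change`, `fdr`; at most one row per (gene, contrast).
#' @param fdr_threshold significance threshold in (0, 1); default 0.1.
#' @return A `gate_result`: list with character vectors
#'   `mosaic_specific_up`, `mosaic_specific_down`, `shared`, plus
#'   `fdr_threshold` and an (initially empty) `annotations` list.
#' @export
gate_de <- function(records, fdr_threshold = 0.1) {
  stopifnot(all(c("gene_id", "contrast", "log2_fold_change", "fdr")
                %in% names(records)))
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stopf("fdr_threshold must lie in (0, 1)")
  contrasts <- c("mosaic_vs_uninjected", "ubiquitous_vs_uninjected")
  bad <- !records$contrast %in% contrasts
  if (any(bad))
    stopf("unknown contrast(s): %s",
          paste(unique(records$contrast[bad]), collapse = ", "))
  key <- paste(records$gene_id, records$contrast)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stopf("duplicate (gene, contrast) rows: %s",
          paste(utils::head(dups, 5), collapse = "; "))
  }
  m <- records[records$contrast == contrasts[1], , drop = FALSE]
  u <- records[records$contrast == contrasts[2], , drop = FALSE]
  sig <- function(df) df$gene_id[!is.na(df$fdr) & df$fdr < fdr_threshold]
  sig_m <- sig(m); sig_u <- sig(u)
  lfc_m <- setNames(m$log2_fold_change, m$gene_id)
  up <- sig_m[!sig_m %in% sig_u & lfc_m[sig_m] > 0]
  down <- sig_m[!sig_m %in% sig_u & lfc_m[sig_m] < 0]
  structure(list(mosaic_specific_up = sort(up),
                 mosaic_specific_down = sort(down),
                 shared = sort(intersect(sig_m, sig_u)),
                 fdr_threshold = fdr_threshold,
                 annotations = list()),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf(paste0("gate_result (FDR < %g): %d mosaic-specific up, ",
                     "%d down, %d shared\n"),
              x$fdr_threshold, length(x$mosaic_specific_up),
              length(x$mosaic_specific_down), length(x$shared)))
  for (nm in names(x$annotations)) {
    a <- x$annotations[[nm]]
    cat(sprintf("  panel %s: up %d, down %d, shared %d\n", nm,
                a$counts["mosaic_specific_up"],
                a$counts["mosaic_specific_down"], a$counts["shared"]))
  }
  invisible(x)
}

#' Annotate gated gene sets against a gene panel
#'
#' Intersects each gated set with a supplied panel (e.g. a curated list of
#' Smad-target genes). Matching is case-normalized.
#'
#' @param result a `gate_result` from [gate_de()].
#' @param panel_name name under which the annotation is stored.
#' @param gene_list non-empty character vector of panel genes.
#' @return The `gate_result` with
#'   `annotations[[panel_name]] = list(members, counts)`, where `members`
#'   maps each gated set to its panel intersection.
#' @export
annotate_gate <- function(result, panel_name, gene_list) {
  stopifnot(inherits(result, "gate_result"))
  if (!length(gene_list)) stopf("panel is empty")
  panel <- unique(tolower(gene_list))
  sets <- c("mosaic_specific_up", "mosaic_specific_down", "shared")
  members <- lapply(sets, function(s)
    result[[s]][tolower(result[[s]]) %in% panel])
  names(members) <- sets
  result$annotations[[panel_name]] <-
    list(members = members, counts = vapply(members, length, integer(1)))
  result
}
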