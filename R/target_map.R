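# Compound-to-target mapping: threshold a table of likelihood scores
# (weighted-ensemble-similarity style output), collect the unique target set
# by UniProt accession, and compute per-side degrees.

#' Threshold compound-target likelihood scores
#'
#' Keeps exactly the pairs whose likelihood score is at least `cutoff`
#' (inclusive, so a score of exactly 7 is accepted under the default).
#' Input order is preserved.
#'
#' @param pairs Data frame with columns `compound_id`, `target_uniprot`,
#'   `likelihood`.
#' @param cutoff Acceptance threshold (default 7).
#' @return The accepted subset of `pairs`.
#' @export
threshold_pairs <- function(pairs, cutoff = 7) {
  stopifnot(is.data.frame(pairs))
  need <- c("compound_id", "target_uniprot", "likelihood")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) {
    stop("pairs lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(pairs$likelihood) || anyNA(pairs$likelihood) ||
      any(!is.finite(pairs$likelihood))) {
    stop("likelihood scores must be finite numbers", call. = FALSE)
  }
  key <- paste(pairs$compound_id, pairs$target_uniprot, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (compound_id, target_uniprot) pair in the score table",
         call. = FALSE)
  }
  out <- pairs[pairs$likelihood >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse accepted pairs into an interaction set
#'
#' Collects the unique target list by UniProt accession (the accession, not
#' the gene symbol, is the target identity) and computes the per-compound and
#' per-target degrees. The two degree sums both equal the number of accepted
#' pairs (the bipartite handshake identity), which is asserted on every call.
#'
#' @param pairs Accepted pairs from [threshold_pairs()] (columns
#'   `compound_id`, `target_uniprot`).
#' @return An object of class `interaction_set`: a list with `pairs`,
#'   `targets` (unique accessions, first-seen order), `compounds`,
#'   `compound_degree` and `target_degree` (named integer vectors),
#'   `n_pairs`, `n_targets`, `n_compounds`.
#' @export
dedupe_targets <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  need <- c("compound_id", "target_uniprot")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) {
    stop("pairs lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cid <- as.character(pairs$compound_id)
  acc <- as.character(pairs$target_uniprot)
  blank <- which(is.na(acc) | !nzchar(trimws(acc)))
  if (length(blank)) {
    stop("blank UniProt accession for compound '", cid[blank[1]],
         "' (row ", blank[1], ")", call. = FALSE)
  }
  key <- paste(cid, acc, sep = "\r")
  keep <- !duplicated(key)
  cid <- cid[keep]; acc <- acc[keep]
  compounds <- unique(cid)
  targets <- unique(acc)
  cdeg <- table(factor(cid, levels = compounds))
  tdeg <- table(factor(acc, levels = targets))
  cdeg <- stats::setNames(as.integer(cdeg), names(cdeg))
  tdeg <- stats::setNames(as.integer(tdeg), names(tdeg))
  n_pairs <- length(cid)
  stopifnot(sum(cdeg) == n_pairs, sum(tdeg) == n_pairs)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(pairs = out, compounds = compounds, targets = targets,
                 compound_degree = cdeg, target_degree = tdeg,
                 n_pairs = n_pairs, n_targets = length(targets),
                 n_compounds = length(compounds)),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("interaction set: %d pairs, %d compounds, %d unique targets\n",
              x$n_pairs, x$n_compounds, x$n_targets))
  invisible(x)
}
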