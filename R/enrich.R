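# Over-representation analysis of a target set against annotation term
# universes (GO-BP, pathway, disease) via the hypergeometric upper tail,
# with optional EASE-style correction and Benjamini-Hochberg adjustment,
# plus the coarse function-module grouping of pathway results.

#' Build a term universe from an annotation table
#'
#' @param annotations Data frame with columns `subject_id`, `term_id` (and
#'   optionally `term_kind`), as from [read_annotation_table()].
#' @param background Optional character vector of background subjects;
#'   defaults to all subjects appearing in `annotations`. Term members
#'   outside the background are dropped.
#' @param term_kind Optional filter: keep only rows of this kind.
#' @return An object of class `term_universe`: list with `background`
#'   (character vector), `terms` (named list of subject subsets), `kind`.
#' @export
term_universe <- function(annotations, background = NULL, term_kind = NULL) {
  stopifnot(is.data.frame(annotations))
  need <- c("subject_id", "term_id")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) {
    stop("annotations lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann <- annotations
  if (!is.null(term_kind) && "term_kind" %in% names(ann)) {
    ann <- ann[!is.na(ann$term_kind) & ann$term_kind == term_kind, ,
               drop = FALSE]
  }
  ann <- unique(data.frame(subject_id = as.character(ann$subject_id),
                           term_id = as.character(ann$term_id),
                           stringsAsFactors = FALSE))
  bg <- if (is.null(background)) unique(ann$subject_id)
        else unique(as.character(background))
  if (length(bg) == 0) stop("empty background", call. = FALSE)
  ann <- ann[ann$subject_id %in% bg, , drop = FALSE]
  terms <- split(ann$subject_id, ann$term_id)
  structure(list(background = bg, terms = terms,
                 kind = if (is.null(term_kind)) NA_character_ else term_kind),
            class = "term_universe")
}

#' Hypergeometric over-representation test
#'
#' For every term with member set of size `K` in a background of size `N`,
#' and a query of size `n` overlapping the term in `k` subjects, computes
#' the upper-tail probability `P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)` — the chance of at least as large an
#' overlap when `n` subjects are drawn without replacement. Query ids
#' outside the background are dropped with a warning that counts them.
#' Results are sorted by p-value, ties broken by term id for stable output.
#'
#' The optional EASE-style correction (`ease = TRUE`) removes one subject
#' from the overlap (`P[X >= k - 1]` with k reduced by one), a conservative
#' variant used by some annotation servers; it is off by default. No
#' multiple-testing correction is applied by default, mirroring a raw
#' `P < 0.05` significance rule; `fdr = TRUE` adds Benjamini-Hochberg
#' q-values (significance still reported on the raw p unless you use the
#' q-values yourself).
#'
#' @param query Character vector of subject ids (e.g. UniProt accessions).
#' @param universe A [term_universe()].
#' @param alpha Significance level on the raw p-value (default 0.05;
#'   significant means `p < alpha`).
#' @param ease Logical; apply the EASE-style `k - 1` correction.
#' @param fdr Logical; add a `q_value` column (Benjamini-Hochberg).
#' @return A data frame of class `enrichment_result` with columns
#'   `term_id`, `k`, `K`, `n`, `N`, `p_value`, (`q_value`,) `significant`,
#'   and a list-column `hits` of the overlapping subjects; attribute
#'   `n_dropped` counts query ids outside the background.
#' @examples
#' ann <- data.frame(subject_id = c("a", "b", "c", "d", "a", "b"),
#'                   term_id = c("t1", "t1", "t1", "t1", "t2", "t2"))
#' u <- term_universe(ann, background = letters[1:10])
#' hypergeom_enrich(c("a", "b"), u)
#' @export
hypergeom_enrich <- function(query, universe, alpha = 0.05,
                             ease = FALSE, fdr = FALSE) {
  stopifnot(inherits(universe, "term_universe"),
            is.numeric(alpha), alpha > 0, alpha <= 1)
  if (length(universe$background) == 0) stop("empty background", call. = FALSE)
  query <- unique(as.character(query))
  in_bg <- query %in% universe$background
  n_dropped <- sum(!in_bg)
  if (n_dropped > 0) {
    warning(n_dropped, " query id(s) outside the background dropped",
            call. = FALSE)
  }
  query <- query[in_bg]
  N <- length(universe$background)
  n <- length(query)
  term_ids <- names(universe$terms)
  res <- lapply(term_ids, function(tid) {
    members <- unique(universe$terms[[tid]])
    K <- length(members)
    hits <- intersect(query, members)
    k <- length(hits)
    k_eff <- if (ease) max(k - 1L, 0L) else k
    # P[X >= k_eff]; k_eff = 0 gives 1 by construction
    p <- stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
    list(term_id = tid, k = k, K = K, n = n, N = N,
         p_value = min(p, 1), hits = hits)
  })
  out <- data.frame(
    term_id = vapply(res, `[[`, character(1), "term_id"),
    k = vapply(res, `[[`, integer(1), "k"),
    K = vapply(res, `[[`, integer(1), "K"),
    n = vapply(res, `[[`, integer(1), "n"),
    N = vapply(res, `[[`, integer(1), "N"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  out$hits <- lapply(res, `[[`, "hits")
  ord <- order(out$p_value, out$term_id)
  out <- out[ord, , drop = FALSE]
  if (fdr) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "alpha") <- alpha
  attr(out, "ease") <- ease
  class(out) <- c("enrichment_result", class(out))
  out
}

# the five default function-module labels for pathway grouping
.function_modules <- c("inflammatory regulation", "immune regulation",
                       "metabolic regulation",
                       "bacterial infection or mycosis", "other function")

#' Group pathway enrichment results into function modules
#'
#' Assigns each pathway term to exactly one coarse function module
#' (inflammatory regulation, immune regulation, metabolic regulation,
#' bacterial infection or mycosis, other function) and summarizes term
#' counts and the pooled set of overlapping targets per module. Pathways
#' absent from the module map fall into `"other function"`; a pathway
#' mapped to two modules is an error, since the map must be a function.
#'
#' @param results An [hypergeom_enrich()] result over pathway terms.
#' @param module_map Data frame with columns `subject_id` (pathway term id)
#'   and `term_id` (module label).
#' @param modules Character vector of module labels to report (the five
#'   defaults always include `"other function"`).
#' @return A data frame with one row per module: `module`, `n_terms`,
#'   `n_significant`, `n_targets`, plus a list-column `targets` (pooled
#'   overlapping subjects).
#' @export
group_by_function_module <- function(results, module_map,
                                     modules = .function_modules) {
  stopifnot(is.data.frame(results), is.data.frame(module_map))
  if (!"other function" %in% modules) modules <- c(modules, "other function")
  if (nrow(module_map)) {
    need <- c("subject_id", "term_id")
    miss <- setdiff(need, names(module_map))
    if (length(miss)) {
      stop("module map lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    mm <- unique(data.frame(subject_id = as.character(module_map$subject_id),
                            term_id = as.character(module_map$term_id),
                            stringsAsFactors = FALSE))
    dup <- mm$subject_id[duplicated(mm$subject_id)]
    if (length(dup)) {
      stop("pathway(s) mapped to more than one module: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
    lookup <- stats::setNames(mm$term_id, mm$subject_id)
  } else {
    lookup <- character(0)
  }
  assigned <- unname(lookup[results$term_id])
  assigned[is.na(assigned)] <- "other function"
  unknown <- setdiff(unique(assigned), modules)
  if (length(unknown)) modules <- c(modules, unknown)
  out <- do.call(rbind, lapply(modules, function(m) {
    sel <- assigned == m
    pooled <- unique(unlist(results$hits[sel], use.names = FALSE))
    if (is.null(pooled)) pooled <- character(0)
    data.frame(module = m, n_terms = sum(sel),
               n_significant = sum(sel & results$significant),
               n_targets = length(pooled), stringsAsFactors = FALSE)
  }))
  out$targets <- lapply(modules, function(m) {
    pooled <- unique(unlist(results$hits[assigned == m], use.names = FALSE))
    if (is.null(pooled)) character(0) else pooled
  })
  rownames(out) <- NULL
  out
}
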