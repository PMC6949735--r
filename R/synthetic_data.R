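# Synthetic TCMSP-like inputs with known ground truth: per-herb ingredient
# catalogues with realistic OB/DL/HL marginals, compound-target likelihood
# matrices with planted hub compounds and hub targets, and annotation
# universes with planted enriched terms. One global seed expands to
# independent per-stage substreams so each stage can be regenerated on its
# own; a fixed seed gives byte-identical output.

# supported marginal distributions for the ADME fields
.check_dist <- function(d, name) {
  if (!is.list(d) || is.null(d$dist)) {
    stop(name, " must be a list with a 'dist' field", call. = FALSE)
  }
  ok <- switch(d$dist,
    lnorm = all(c("meanlog", "sdlog") %in% names(d)),
    beta  = all(c("shape1", "shape2") %in% names(d)),
    gamma = all(c("shape", "scale") %in% names(d)),
    norm  = all(c("mean", "sd") %in% names(d)),
    point = "value" %in% names(d),
    stop("unsupported distribution '", d$dist, "' for ", name, call. = FALSE))
  if (!ok) stop("missing parameters for ", name, " (", d$dist, ")", call. = FALSE)
  d
}

.draw_dist <- function(d, n) {
  switch(d$dist,
    lnorm = stats::rlnorm(n, d$meanlog, d$sdlog),
    beta  = stats::rbeta(n, d$shape1, d$shape2),
    gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
    norm  = stats::rnorm(n, d$mean, d$sd),
    point = rep(d$value, n))
}

# P[X >= q] under the configured marginal (continuous: boundary mass 0)
.prob_ge <- function(d, q) {
  switch(d$dist,
    lnorm = stats::plnorm(q, d$meanlog, d$sdlog, lower.tail = FALSE),
    beta  = stats::pbeta(q, d$shape1, d$shape2, lower.tail = FALSE),
    gamma = stats::pgamma(q, shape = d$shape, scale = d$scale,
                          lower.tail = FALSE),
    norm  = stats::pnorm(q, d$mean, d$sd, lower.tail = FALSE),
    point = as.numeric(d$value >= q))
}

.prob_between <- function(d, lo, hi) {
  if (d$dist == "point") return(as.numeric(d$value >= lo && d$value <= hi))
  .prob_ge(d, lo) - .prob_ge(d, hi)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the shape of a four-herb formula study: 190/87/57/48
#' ingredients per herb (382 total); OB drawn from a right-skewed lognormal
#' with median 25%; DL from a Beta(2, 5) with mode 0.2; HL from a
#' gamma(shape 2, scale 3 h) with median about 6 h — together these put the
#' analytic pass rate of the default OB/DL/HL screen near 10%
#' (see [screen_pass_rate()]). The likelihood matrix covers 41 compounds by
#' 94 targets with one planted hub compound of 73 true targets and one
#' planted hub target of 34 true compounds; true pairs score N(9, 1) and
#' background pairs N(3, 1.5), so a score cutoff of 7 separates them
#' sharply. The annotation universe has 50 pathway terms over the targets,
#' one planted term enriched in a 20-target query set at odds 20.
#'
#' @param seed Integer master seed; expanded into independent substreams for
#'   the catalogue, likelihood and annotation stages.
#' @param herbs Named integer vector: ingredients per herb.
#' @param ob_dist,dl_dist,hl_dist Marginals for OB (%), DL and HL (hours):
#'   lists with a `dist` field (`"lnorm"`, `"beta"`, `"gamma"`, `"norm"`,
#'   `"point"`) and its parameters.
#' @param n_compounds,n_targets Dimensions of the likelihood matrix.
#' @param hub_compounds List of `c(index, target_count)` pairs: compound
#'   `index` receives exactly `target_count` true targets.
#' @param hub_targets List of `c(index, compound_count)` pairs: target
#'   `index` receives `compound_count` true compounds (drawn from non-hub
#'   compounds; exact when no hub compound row later adds to the column).
#' @param true_rate Background probability that a non-planted pair is true.
#' @param likelihood_true,likelihood_bg Score distributions for true and
#'   background pairs.
#' @param n_terms Number of annotation terms.
#' @param term_subject_prob Baseline inclusion probability of a subject in
#'   a term.
#' @param planted_terms List of `c(term_index, odds)` pairs: the term
#'   over-represents the designated query set with the given odds ratio on
#'   inclusion.
#' @param n_query Size of the designated query subject set used by planted
#'   terms.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       herbs = c("Panax ginseng" = 190,
                                 "Astragalus membranaceus" = 87,
                                 "Pulsatilla chinensis" = 57,
                                 "Coptis chinensis" = 48),
                       ob_dist = list(dist = "lnorm", meanlog = log(25), sdlog = 0.8),
                       dl_dist = list(dist = "beta", shape1 = 2, shape2 = 5),
                       hl_dist = list(dist = "gamma", shape = 2, scale = 3),
                       n_compounds = 41, n_targets = 94,
                       hub_compounds = list(c(1, 73)),
                       hub_targets = list(c(1, 34)),
                       true_rate = 0.02,
                       likelihood_true = list(dist = "norm", mean = 9, sd = 1),
                       likelihood_bg = list(dist = "norm", mean = 3, sd = 1.5),
                       n_terms = 50, term_subject_prob = 0.15,
                       planted_terms = list(c(1, 20)),
                       n_query = 20) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  herbs <- unlist(herbs)
  if (is.null(names(herbs)) || any(!nzchar(names(herbs)))) {
    stop("herbs must be a named vector of ingredient counts", call. = FALSE)
  }
  if (any(herbs < 0) || any(herbs != floor(herbs))) {
    stop("ingredient counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(n_compounds >= 0, n_targets >= 0, n_terms >= 0,
            true_rate >= 0, true_rate <= 1,
            term_subject_prob >= 0, term_subject_prob <= 1,
            n_query >= 0, n_query <= n_targets)
  check_hubs <- function(h, max_index, max_count, what) {
    if (length(h) == 0) return(invisible())
    idx <- vapply(h, `[`, numeric(1), 1)
    cnt <- vapply(h, `[`, numeric(1), 2)
    if (any(idx < 1 | idx > max_index)) {
      stop("planted ", what, " index out of range", call. = FALSE)
    }
    if (anyDuplicated(idx)) {
      stop("overlapping hub specifications: duplicate ", what, " index",
           call. = FALSE)
    }
    if (any(cnt < 0 | cnt > max_count)) {
      stop("planted ", what, " count out of range", call. = FALSE)
    }
  }
  check_hubs(hub_compounds, n_compounds, n_targets, "hub-compound")
  check_hubs(hub_targets, n_targets, n_compounds, "hub-target")
  if (length(planted_terms)) {
    idx <- vapply(planted_terms, `[`, numeric(1), 1)
    odds <- vapply(planted_terms, `[`, numeric(1), 2)
    if (n_terms < length(planted_terms) || any(idx < 1 | idx > n_terms)) {
      stop("planted term index out of range", call. = FALSE)
    }
    if (any(odds <= 0)) stop("enrichment odds must be positive", call. = FALSE)
    if (anyDuplicated(idx)) stop("duplicate planted term index", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), herbs = herbs,
    ob_dist = .check_dist(ob_dist, "ob_dist"),
    dl_dist = .check_dist(dl_dist, "dl_dist"),
    hl_dist = .check_dist(hl_dist, "hl_dist"),
    n_compounds = as.integer(n_compounds), n_targets = as.integer(n_targets),
    hub_compounds = hub_compounds, hub_targets = hub_targets,
    true_rate = true_rate,
    likelihood_true = .check_dist(likelihood_true, "likelihood_true"),
    likelihood_bg = .check_dist(likelihood_bg, "likelihood_bg"),
    n_terms = as.integer(n_terms), term_subject_prob = term_subject_prob,
    planted_terms = planted_terms, n_query = as.integer(n_query)
  ), class = "sim_config")
}

# independent per-stage seeds derived from the master seed
.substream_seeds <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 3),
                  c("catalogue", "likelihood", "annotation"))
}

#' Generate a synthetic ingredient catalogue
#'
#' Draws the requested number of ingredients per herb with OB/DL/HL sampled
#' from the configured marginals and plausible values for the remaining
#' TCMSP descriptor fields. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A data frame in [read_ingredient_catalogue()] layout, one row per
#'   ingredient, herbs in configuration order.
#' @export
gen_catalogue <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seeds(config)[["catalogue"]])
  n <- sum(config$herbs)
  herb <- rep(names(config$herbs), times = config$herbs)
  if (n == 0) {
    return(data.frame(ingredient_id = character(0), name = character(0),
                      herb = character(0), mw = numeric(0), alogp = numeric(0),
                      hdon = numeric(0), hacc = numeric(0), ob = numeric(0),
                      caco2 = numeric(0), bbb = numeric(0), dl = numeric(0),
                      fasa = numeric(0), hl = numeric(0),
                      stringsAsFactors = FALSE))
  }
  id <- sprintf("sim%03d", seq_len(n))
  data.frame(
    ingredient_id = id,
    name = paste("synthetic compound", seq_len(n)),
    herb = herb,
    mw = stats::rlnorm(n, log(350), 0.4),
    alogp = stats::rnorm(n, 2, 2),
    hdon = stats::rpois(n, 2),
    hacc = stats::rpois(n, 5),
    ob = .draw_dist(config$ob_dist, n),
    caco2 = stats::rnorm(n, 0.5, 0.8),
    bbb = stats::rnorm(n, -0.3, 1),
    dl = pmin(pmax(.draw_dist(config$dl_dist, n), 0), 1),
    fasa = stats::rbeta(n, 2, 8),
    hl = .draw_dist(config$hl_dist, n),
    stringsAsFactors = FALSE
  )
}

#' Analytic pass rate of the screen under a configuration
#'
#' Closed-form probability that one simulated ingredient passes the given
#' criteria, from the configured OB/DL/HL marginals (drawn independently):
#' `P(OB >= ob_min) * P(DL >= dl_min) * P(hl_min <= HL <= hl_max)`.
#' The empirical pass rate of [screen()] on a [gen_catalogue()] draw
#' converges to this value (binomially).
#'
#' @param config A [sim_config()].
#' @param criteria A [screening_criteria()].
#' @return A probability.
#' @export
screen_pass_rate <- function(config, criteria = screening_criteria()) {
  stopifnot(inherits(config, "sim_config"),
            inherits(criteria, "screening_criteria"))
  .prob_ge(config$ob_dist, criteria$ob_min) *
    .prob_ge(config$dl_dist, criteria$dl_min) *
    .prob_between(config$hl_dist, criteria$hl_min, criteria$hl_max)
}

#' Generate a synthetic compound-target likelihood matrix
#'
#' Enumerates `n_compounds x n_targets` pairs. Background pairs are true
#' with probability `true_rate`; each planted hub target then receives
#' exactly its configured number of true compounds (drawn from non-hub
#' compounds), and each planted hub compound exactly its configured number
#' of true targets (its row is overwritten, so the row count is exact).
#' True pairs draw their likelihood score from `likelihood_true`,
#' background pairs from `likelihood_bg`; with the default continuous
#' distributions, ties at a score threshold have probability zero.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `compound_id`, `target_uniprot`,
#'   `likelihood`, `is_true`, in row-major (compound, target) order.
#' @export
gen_likelihood_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seeds(config)[["likelihood"]])
  nc <- config$n_compounds; nt <- config$n_targets
  compounds <- sprintf("cmp%03d", seq_len(nc))
  targets <- sprintf("T%03d", seq_len(nt))
  truth <- matrix(stats::runif(nc * nt) < config$true_rate, nc, nt)
  hub_c_idx <- vapply(config$hub_compounds, `[`, numeric(1), 1)
  for (h in config$hub_targets) {
    j <- h[1]; cnt <- h[2]
    pool <- setdiff(seq_len(nc), hub_c_idx)
    if (length(pool) < cnt) {
      stop("hub-target count exceeds available non-hub compounds", call. = FALSE)
    }
    truth[, j] <- FALSE
    truth[sample(pool, cnt), j] <- TRUE
  }
  for (h in config$hub_compounds) {
    i <- h[1]; cnt <- h[2]
    truth[i, ] <- FALSE
    truth[i, sample(nt, cnt)] <- TRUE
  }
  is_true <- as.vector(t(truth)) # row-major: compound varies slowest
  n_pairs <- nc * nt
  score <- numeric(n_pairs)
  score[is_true] <- .draw_dist(config$likelihood_true, sum(is_true))
  score[!is_true] <- .draw_dist(config$likelihood_bg, sum(!is_true))
  data.frame(
    compound_id = rep(compounds, each = nt),
    target_uniprot = rep(targets, times = nc),
    likelihood = score,
    is_true = is_true,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic annotation universe with planted enriched terms
#'
#' Subjects are the configured targets. Background terms include each
#' subject independently with probability `term_subject_prob`; a planted
#' term raises the inclusion probability of the designated query set to
#' `odds * p / (1 - p + odds * p)` (an odds-ratio bump on inclusion), so
#' `odds = 1` reduces every term to background and the enrichment stage
#' sees a pure null.
#'
#' @param config A [sim_config()].
#' @return A list with `annotations` (data frame `subject_id`, `term_id`,
#'   `term_kind = "pathway"`), and `truth`: `planted_terms` (term ids),
#'   `query` (the designated subject set), `background` (all subjects).
#' @export
gen_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seeds(config)[["annotation"]])
  subjects <- sprintf("T%03d", seq_len(config$n_targets))
  term_ids <- sprintf("term%03d", seq_len(config$n_terms))
  query <- sort(sample(subjects, config$n_query))
  p0 <- config$term_subject_prob
  planted_idx <- vapply(config$planted_terms, `[`, numeric(1), 1)
  planted_odds <- vapply(config$planted_terms, `[`, numeric(1), 2)
  rows_s <- character(0); rows_t <- character(0)
  for (t in seq_len(config$n_terms)) {
    p <- rep(p0, length(subjects))
    hit <- match(t, planted_idx)
    if (!is.na(hit)) {
      odds <- planted_odds[hit]
      p_plant <- odds * p0 / (1 - p0 + odds * p0)
      p[subjects %in% query] <- p_plant
    }
    member <- stats::runif(length(subjects)) < p
    rows_s <- c(rows_s, subjects[member])
    rows_t <- c(rows_t, rep(term_ids[t], sum(member)))
  }
  ann <- data.frame(subject_id = rows_s, term_id = rows_t,
                    term_kind = rep("pathway", length(rows_s)),
                    stringsAsFactors = FALSE)
  list(annotations = ann,
       truth = list(planted_terms = term_ids[planted_idx],
                    query = query, background = subjects))
}

#' Write one full simulated input set to a directory
#'
#' Emits `catalogue.tsv`, `scores.tsv` and `annotations.tsv` in the dialects
#' the readers of this package accept, plus `truth.json` with the planted
#' ground truth. Byte-identical across runs for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cat_df <- gen_catalogue(config)
  pairs <- gen_likelihood_matrix(config)
  ann <- gen_annotations(config)
  paths <- c(catalogue = file.path(out_dir, "catalogue.tsv"),
             scores = file.path(out_dir, "scores.tsv"),
             annotations = file.path(out_dir, "annotations.tsv"),
             truth = file.path(out_dir, "truth.json"))
  .write_tsv <- function(df, path, digits = 6) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, digits))
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  .write_tsv(cat_df, paths[["catalogue"]])
  .write_tsv(pairs, paths[["scores"]])
  .write_tsv(ann$annotations, paths[["annotations"]])
  jsonlite::write_json(ann$truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
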