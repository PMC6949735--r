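# Tabular ingestion/emission for ingredient catalogues, target tables,
# annotation tables and edge lists. All readers are UTF-8 and accept TSV or
# CSV (sniffed from the extension, or forced via `sep`). Column-name matching
# is case-insensitive through a synonym map because TCMSP-style exports vary
# in their headers ("OB (%)", "Mol ID", ...).

# canonical name -> accepted header spellings (lowercased, stripped of
# spaces/%/parentheses before lookup)
.col_synonyms <- list(
  ingredient_id = c("ingredient_id", "id", "molid", "moleculeid", "mol"),
  name          = c("name", "compound", "compounds", "moleculename", "ingredient"),
  herb          = c("herb", "herbs", "source"),
  mw            = c("mw", "molecularweight"),
  alogp         = c("alogp"),
  hdon          = c("hdon", "hodn", "hbd"),
  hacc          = c("hacc", "hba"),
  ob            = c("ob"),
  caco2         = c("caco2", "caco-2", "caco"),
  bbb           = c("bbb"),
  dl            = c("dl", "druglikeness"),
  fasa          = c("fasa", "fasa-"),
  hl            = c("hl", "halflife"),
  degree        = c("degree"),
  uniprot_ac    = c("uniprot_ac", "uniprot", "uniprotac", "accession", "ac"),
  protein_name  = c("protein_name", "proteinname", "proteinnames", "protein"),
  gene_symbol   = c("gene_symbol", "genesymbol", "genenames", "gene", "genes", "symbol"),
  organism      = c("organism", "species")
)

.squash <- function(x) gsub("[^a-z0-9_-]", "", tolower(x))

# map raw headers to canonical names; unmatched headers pass through untouched
.canonical_names <- function(headers) {
  sq <- .squash(headers)
  out <- headers
  for (canon in names(.col_synonyms)) {
    hit <- which(sq %in% .squash(.col_synonyms[[canon]]))
    if (length(hit)) out[hit[1]] <- canon
  }
  out
}

.sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_table_raw <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = .sniff_sep(path, sep), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8", na.strings = c("NA", ""),
                    quote = "")
}

# coerce a column to numeric, reporting 1-based data-row numbers on failure
.numeric_col <- function(df, col, path) {
  x <- df[[col]]
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s' at row %d of %s",
                 x[bad[1]], col, bad[1], path), call. = FALSE)
  }
  out
}

#' Read a TCMSP-style ingredient catalogue
#'
#' Parses a TSV/CSV export with one row per herb ingredient. Headers are
#' matched case-insensitively against a synonym map (e.g. `"OB (%)"` is
#' accepted for `ob`). Mandatory columns are `ingredient_id`, `name`, `ob`,
#' `dl` and `hl`; the remaining ADME descriptors (`mw`, `alogp`, `hdon`,
#' `hacc`, `caco2`, `bbb`, `fasa`) are optional and recorded as `NA` when
#' absent — never as zero, since 0 is a legal OB/DL value.
#'
#' @param path Path to the TSV/CSV file (UTF-8).
#' @param herb Optional herb name stamped onto every record; if `NULL`, a
#'   `herb` column in the file is used (multiple herbs separated by `"; "`),
#'   else the herb is recorded as `NA`.
#' @param sep Field separator; defaults to `"\t"` (`","` for `.csv`).
#' @return A data frame with columns `ingredient_id`, `name`, `herb`, `mw`,
#'   `alogp`, `hdon`, `hacc`, `ob`, `caco2`, `bbb`, `dl`, `fasa`, `hl`
#'   (plus `degree` if the file carries one), one row per ingredient, in
#'   file order.
#' @examples
#' path <- system.file("extdata", "table1.tsv", package = "herbnet")
#' cat41 <- read_ingredient_catalogue(path)
#' nrow(cat41)
#' @export
read_ingredient_catalogue <- function(path, herb = NULL, sep = NULL) {
  df <- .read_table_raw(path, sep)
  names(df) <- .canonical_names(names(df))
  mandatory <- c("ingredient_id", "name", "ob", "dl", "hl")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("ingredient catalogue is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  optional <- c("mw", "alogp", "hdon", "hacc", "caco2", "bbb", "fasa")
  for (col in optional) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  }
  for (col in c("ob", "dl", "hl", optional)) df[[col]] <- .numeric_col(df, col, path)
  if ("degree" %in% names(df)) df$degree <- .numeric_col(df, "degree", path)

  df$ingredient_id <- as.character(df$ingredient_id)
  dup <- df$ingredient_id[duplicated(df$ingredient_id)]
  if (length(dup)) {
    stop("duplicated ingredient_id in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!is.null(herb)) {
    df$herb <- rep(herb, nrow(df))
  } else if (!"herb" %in% names(df)) {
    df$herb <- rep(NA_character_, nrow(df))
  }
  bad_ob <- which(!is.na(df$ob) & df$ob < 0)
  bad_dl <- which(!is.na(df$dl) & (df$dl < 0 | df$dl > 1))
  bad_hl <- which(!is.na(df$hl) & df$hl < 0)
  if (length(c(bad_ob, bad_dl, bad_hl))) {
    stop("out-of-range ADME value (ob < 0, dl outside [0, 1], or hl < 0) at row(s) ",
         paste(sort(unique(c(bad_ob, bad_dl, bad_hl))), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  keep <- c("ingredient_id", "name", "herb", "mw", "alogp", "hdon", "hacc",
            "ob", "caco2", "bbb", "dl", "fasa", "hl",
            intersect("degree", names(df)))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a UniProt target table
#'
#' Parses a table of protein targets with columns `uniprot_ac`,
#' `protein_name` and `gene_symbol` (synonym headers accepted). Gene symbols
#' are normalized to uppercase; duplicate accessions are rejected because the
#' UniProt accession is the target identity.
#'
#' @inheritParams read_ingredient_catalogue
#' @return A data frame with columns `uniprot_ac`, `protein_name`,
#'   `gene_symbol`, `organism` (plus `degree` if present), in file order.
#' @examples
#' path <- system.file("extdata", "table2.tsv", package = "herbnet")
#' targets <- read_target_table(path)
#' subset(targets, uniprot_ac == "P03372")$gene_symbol
#' @export
read_target_table <- function(path, sep = NULL) {
  df <- .read_table_raw(path, sep)
  names(df) <- .canonical_names(names(df))
  mandatory <- c("uniprot_ac", "protein_name", "gene_symbol")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("target table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$uniprot_ac <- as.character(df$uniprot_ac)
  dup <- df$uniprot_ac[duplicated(df$uniprot_ac)]
  if (length(dup)) {
    stop("duplicated UniProt accession in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df$gene_symbol <- toupper(as.character(df$gene_symbol))
  if (!"organism" %in% names(df)) df$organism <- NA_character_
  if ("degree" %in% names(df)) df$degree <- .numeric_col(df, "degree", path)
  keep <- c("uniprot_ac", "protein_name", "gene_symbol", "organism",
            intersect("degree", names(df)))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read an annotation table
#'
#' Loads rows of `(subject_id, term_id, term_kind)` linking subjects (usually
#' UniProt targets) to disease, pathway, GO-BP or function-module terms.
#' Duplicate `(subject_id, term_id)` rows are collapsed.
#'
#' @inheritParams read_ingredient_catalogue
#' @param term_kind Optional kind (`"disease"`, `"pathway"`, `"go_bp"`,
#'   `"function_module"`) stamped onto rows when the file has no
#'   `term_kind` column.
#' @return A data frame with columns `subject_id`, `term_id`, `term_kind`.
#' @export
read_annotation_table <- function(path, term_kind = NULL, sep = NULL) {
  df <- .read_table_raw(path, sep)
  names(df) <- tolower(names(df))
  mandatory <- c("subject_id", "term_id")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("annotation table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"term_kind" %in% names(df)) {
    df$term_kind <- if (is.null(term_kind)) NA_character_ else term_kind
  }
  df <- df[, c("subject_id", "term_id", "term_kind")]
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Write a bipartite edge list
#'
#' Emits edges as two/three-column TSV (`left`, `right`, optional `weight`)
#' or Cytoscape SIF (`left <interaction> right`). SIF has no quoting
#' convention, so identifiers containing the delimiter are rejected rather
#' than silently mangled.
#'
#' @param edges Data frame whose first two columns are the left and right
#'   node identifiers; an optional third column is a numeric weight.
#' @param path Output path.
#' @param dialect `"tsv"` or `"sif"`.
#' @param interaction Interaction label used in the SIF dialect
#'   (default `"ct"`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, dialect = c("tsv", "sif"),
                            interaction = "ct") {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  left <- as.character(edges[[1]])
  right <- as.character(edges[[2]])
  delim <- "\t"
  if (any(grepl(delim, c(left, right), fixed = TRUE))) {
    stop("edge identifier contains the column delimiter; refusing to write",
         call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (dialect == "tsv") {
    has_w <- ncol(edges) >= 3
    header <- if (has_w) "left\tright\tweight" else "left\tright"
    lines <- if (nrow(edges) == 0) character(0) else if (has_w) {
      paste(left, right, format(edges[[3]], trim = TRUE, scientific = FALSE),
            sep = "\t")
    } else paste(left, right, sep = "\t")
    writeLines(c(header, lines), con, useBytes = TRUE)
  } else {
    if (any(grepl("[\t ]", interaction))) {
      stop("SIF interaction label must not contain whitespace", call. = FALSE)
    }
    lines <- if (nrow(edges) == 0) character(0) else
      paste(left, interaction, right, sep = "\t")
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path Path to a TSV (`left`/`right`(/`weight`) header) or SIF file.
#' @param dialect `"tsv"` or `"sif"`; sniffed from the extension by default.
#' @return A data frame with columns `left`, `right` (and `weight` for
#'   3-column TSV; `interaction` for SIF).
#' @export
read_edge_list <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  dialect <- match.arg(dialect, c("tsv", "sif"))
  if (dialect == "tsv") {
    df <- .read_table_raw(path, "\t")
    names(df)[1:2] <- c("left", "right")
    return(df)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(left = character(0), interaction = character(0),
                      right = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("malformed SIF line (expected 3 tab-separated fields) in ", path,
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(left = m[, 1], interaction = m[, 2], right = m[, 3],
             stringsAsFactors = FALSE)
}

#' Locate a packaged data file
#'
#' @param file File name under the package's `extdata/` resources.
#' @return Absolute path to the file.
#' @export
herbnet_extdata <- function(file) {
  path <- system.file("extdata", file, package = "herbnet")
  if (!nzchar(path)) stop("no packaged file named '", file, "'", call. = FALSE)
  path
}

#' Packaged formula tables
#'
#' `table1_fixture()` returns the 41-compound bioactive-ingredient table of
#' the worked four-herb ulcerative-colitis formula (id, name, OB, DL, HL,
#' compound-target degree, source herb); `table2_fixture()` returns its
#' 94-target UniProt table (accession, protein name, gene symbol, degree,
#' organism — the organism string is kept exactly as published, including
#' its "Homosapiens" spelling). Both degree columns sum to 367, the size of
#' the compound-target network.
#'
#' @return A data frame (see [read_ingredient_catalogue()] /
#'   [read_target_table()] for columns).
#' @export
table1_fixture <- function() {
  read_ingredient_catalogue(herbnet_extdata("table1.tsv"))
}

#' @rdname table1_fixture
#' @export
table2_fixture <- function() {
  read_target_table(herbnet_extdata("table2.tsv"))
}
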