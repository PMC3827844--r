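#' Construct an expression dataset
#'
#' Container for one platform's probe-by-sample intensity matrix together
#' with per-sample condition (`control`/`disease`) and subset labels. Subsets
#' are either tissue regions that each contain both conditions (the
#' entorhinal-cortex/hippocampus style of design) or condition-pure cohort
#' splits (controls 1-85 vs 86-178 style); both are supported downstream.
#'
#' @param intensities Numeric matrix, probes in rows (rownames are probe ids),
#'   samples in columns (colnames are sample ids). Non-negative arbitrary
#'   units on a linear scale; `NA` marks missing values.
#' @param samples Data frame with columns `sample_id`, `condition`
#'   (`"control"` or `"disease"`) and `subset`.
#' @param platform_id Single string identifying the platform.
#' @return An object of class `cdm_dataset`.
#' @export
cdm_dataset <- function(intensities, samples, platform_id) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "condition", "subset") %in% names(samples))) {
    abort_validation("`samples` must have columns sample_id, condition, subset")
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$subset <- as.character(samples$subset)
  bad <- setdiff(unique(samples$condition), c("control", "disease"))
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "unknown condition label(s): %s (expected 'control' or 'disease')",
      paste(bad, collapse = ", ")
    ))
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    abort_validation("`intensities` must have probe rownames and sample colnames")
  }
  missing_meta <- setdiff(colnames(intensities), samples$sample_id)
  if (length(missing_meta) > 0) {
    abort_validation(sprintf(
      "sample(s) present in the matrix but absent from metadata: %s",
      paste(missing_meta, collapse = ", ")
    ))
  }
  samples <- samples[match(colnames(intensities), samples$sample_id), ]
  if (anyDuplicated(rownames(intensities))) {
    abort_validation("duplicated probe ids in intensity matrix")
  }
  finite <- intensities[!is.na(intensities)]
  if (any(!is.finite(finite))) abort_validation("intensities must be finite or NA")
  if (any(finite < 0)) abort_validation("intensities must be non-negative")
  structure(
    list(
      platform_id = as.character(platform_id)[1],
      intensities = intensities,
      samples = samples
    ),
    class = "cdm_dataset"
  )
}

#' @export
print.cdm_dataset <- function(x, ...) {
  cat(sprintf(
    "<cdm_dataset> platform %s: %d probes x %d samples (%d control / %d disease; subsets: %s)\n",
    x$platform_id, nrow(x$intensities), ncol(x$intensities),
    sum(x$samples$condition == "control"), sum(x$samples$condition == "disease"),
    paste(unique(x$samples$subset), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.cdm_dataset <- function(x) dim(x$intensities)

#' Read a tab-delimited expression matrix with sample metadata
#'
#' The matrix file has probe ids in the first column and one column per
#' sample; the metadata file maps `sample_id` to `condition` and `subset`
#' (optionally `platform`). Both readers tolerate CRLF line endings and
#' comment lines starting with `#`. Every sample column must be described in
#' the metadata; unmatched samples are an error, as are non-numeric cells.
#'
#' @param path Path to the intensity matrix TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param platform_id Platform identifier; defaults to the metadata
#'   `platform` column when present, else `"platform1"`.
#' @return A [cdm_dataset()].
#' @export
read_expression_matrix <- function(path, metadata_path, platform_id = NULL) {
  raw <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(raw) < 2) abort_parse("expression matrix needs a probe id column and >= 1 sample column")
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort_parse(sprintf(
      "malformed expression matrix at row %d: %s",
      probs$row[1], probs$expected[1]
    ))
  }
  probe_ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat), dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !is.na(mat) & !(trimws(mat) %in% c("", "NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_parse(sprintf(
      "non-numeric cell '%s' at row %d (probe %s), column %d (%s)",
      mat[bad[1, 1], bad[1, 2]], bad[1, 1], probe_ids[bad[1, 1]],
      bad[1, 2], colnames(mat)[bad[1, 2]]
    ))
  }
  rownames(num) <- probe_ids

  meta <- readr::read_tsv(
    metadata_path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("sample_id", "condition", "subset") %in% names(meta))) {
    abort_validation("metadata must have columns sample_id, condition, subset")
  }
  if (is.null(platform_id)) {
    platform_id <- if ("platform" %in% names(meta)) meta$platform[1] else "platform1"
  }
  cdm_dataset(num, meta, platform_id)
}

#' Write an expression dataset back to TSV
#'
#' Inverse of [read_expression_matrix()]: canonical fixtures round-trip
#' byte-identically.
#'
#' @param dataset A [cdm_dataset()].
#' @param path Matrix output path.
#' @param metadata_path Optional metadata output path.
#' @return `dataset`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path, metadata_path = NULL) {
  out <- tibble::as_tibble(dataset$intensities, rownames = "probe_id")
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(metadata_path)) {
    meta <- dataset$samples
    meta$platform <- dataset$platform_id
    readr::write_tsv(meta, metadata_path, progress = FALSE)
  }
  invisible(dataset)
}

#' Read a probe annotation table
#'
#' Tab-delimited with columns `probe_id`, `gene_symbol` and optionally
#' `platform_id`. Symbols are normalized (uppercase, trimmed); a probe may map
#' to at most one symbol.
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with columns `probe_id`, `gene_symbol`, `platform_id`.
#' @export
read_probe_annotation <- function(path) {
  ann <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("probe_id", "gene_symbol") %in% names(ann))) {
    abort_validation("annotation must have columns probe_id, gene_symbol")
  }
  if (!"platform_id" %in% names(ann)) ann$platform_id <- NA_character_
  ann$gene_symbol <- normalize_gene_symbols(ann$gene_symbol)
  ann <- ann[ann$gene_symbol != "", c("probe_id", "gene_symbol", "platform_id")]
  key <- paste(ann$probe_id, ann$platform_id)
  if (anyDuplicated(key)) {
    abort_validation("a probe maps to more than one gene symbol in the annotation")
  }
  tibble::as_tibble(ann)
}

#' Read gene sets in GMT format
#'
#' One term per line: `term_id <TAB> description <TAB> member...`. Member
#' symbols are normalized; terms without members are dropped with a warning;
#' duplicated term ids are an error.
#'
#' @param path Path to the GMT file.
#' @return Tibble of class `cdm_gene_sets` with columns `term_id`,
#'   `term_name` and list-column `members`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map2(fields, line_no, function(f, i) {
    if (length(f) == 0) abort_parse(sprintf("malformed GMT line %d: no fields", i))
    members <- if (length(f) > 2) unique(normalize_gene_symbols(f[-(1:2)])) else character()
    members <- members[members != ""]
    tibble::tibble(
      term_id = f[1],
      term_name = if (length(f) >= 2) f[2] else f[1],
      members = list(members)
    )
  })
  sets <- dplyr::bind_rows(rows)
  if (nrow(sets) == 0) {
    sets <- tibble::tibble(term_id = character(), term_name = character(), members = list())
  }
  empty <- lengths(sets$members) == 0
  if (any(empty)) {
    warn(sprintf(
      "dropping %d gene set(s) with no members: %s",
      sum(empty), paste(sets$term_id[empty], collapse = ", ")
    ))
    sets <- sets[!empty, ]
  }
  if (anyDuplicated(sets$term_id)) {
    abort_validation(sprintf(
      "duplicated term id(s): %s",
      paste(unique(sets$term_id[duplicated(sets$term_id)]), collapse = ", ")
    ))
  }
  structure(sets, class = c("cdm_gene_sets", class(sets)))
}

#' Write gene sets to GMT
#'
#' @param gene_sets A `cdm_gene_sets` tibble.
#' @param path Output path.
#' @return `gene_sets`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- purrr::pmap_chr(
    gene_sets[c("term_id", "term_name", "members")],
    function(term_id, term_name, members) {
      paste(c(term_id, term_name, members), collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(gene_sets)
}

#' Read an interaction edge list
#'
#' Two-column (optionally three-column typed) tab-delimited undirected edges.
#' Node symbols are normalized, self-loops removed and duplicate edges
#' collapsed.
#'
#' @param path Path to the edge list.
#' @param keep_isolates Keep nodes whose only edges were self-loops.
#' @return An undirected [igraph::graph] object.
#' @export
read_edge_list <- function(path, keep_isolates = FALSE) {
  edges <- readr::read_tsv(
    path,
    comment = "#", col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(edges) == 0) return(igraph::make_empty_graph(directed = FALSE))
  if (ncol(edges) < 2) abort_parse("edge list must have at least 2 tab-separated columns")
  from <- normalize_gene_symbols(edges[[1]])
  to <- normalize_gene_symbols(edges[[2]])
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = FALSE,
    vertices = if (keep_isolates) sort(unique(c(from, to))) else NULL
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!keep_isolates) g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  g
}

#' Write an edge list
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @return `graph`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  readr::write_tsv(
    tibble::tibble(from = el[, 1], to = el[, 2]),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(graph)
}

#' Read an offline literature corpus
#'
#' Tab-delimited stand-in for abstract-level literature queries:
#' `document_id <TAB> gene;gene;... <TAB> tag;tag;...`. Gene symbols are
#' normalized; the tag vocabulary is the set of tags observed.
#'
#' @param path Path to the corpus TSV.
#' @return Tibble of class `cdm_corpus` with columns `document_id`, list
#'   columns `genes` and `tags`, and a `vocabulary` attribute.
#' @export
read_corpus <- function(path) {
  raw <- readr::read_tsv(
    path,
    comment = "#", col_names = c("document_id", "genes", "tags"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) abort_validation("corpus must contain at least one document")
  split_field <- function(x) {
    purrr::map(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), function(v) {
      v <- trimws(v)
      v[nzchar(v)]
    })
  }
  out <- tibble::tibble(
    document_id = raw$document_id,
    genes = purrr::map(split_field(raw$genes), normalize_gene_symbols),
    tags = split_field(raw$tags)
  )
  as_cdm_corpus(out)
}

as_cdm_corpus <- function(docs) {
  docs$genes <- purrr::map(docs$genes, normalize_gene_symbols)
  vocab <- sort(unique(unlist(docs$tags)))
  structure(docs, class = c("cdm_corpus", class(tibble::as_tibble(docs))), vocabulary = vocab)
}

#' Write a literature corpus
#'
#' @param corpus A `cdm_corpus` tibble.
#' @param path Output path.
#' @return `corpus`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  out <- tibble::tibble(
    document_id = corpus$document_id,
    genes = purrr::map_chr(corpus$genes, paste, collapse = ";"),
    tags = purrr::map_chr(corpus$tags, paste, collapse = ";")
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(corpus)
}

#' Turn an expression dataset into a long tibble
#'
#' @param x A [cdm_dataset()].
#' @param ... Unused.
#' @return Tibble with one row per probe/sample pair.
#' @export
tidy.cdm_dataset <- function(x, ...) {
  long <- tibble::as_tibble(x$intensities, rownames = "probe_id")
  long <- tidyr::pivot_longer(long, -"probe_id",
    names_to = "sample_id", values_to = "intensity"
  )
  long <- dplyr::left_join(long, x$samples, by = "sample_id")
  long$platform_id <- x$platform_id
  long
}
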