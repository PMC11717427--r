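#' @importFrom stats as.dist hclust rhyper setNames
#' @importFrom utils read.delim write.table
NULL

VALID_CATEGORIES <- c("mRNA", "smallRNA", "totalRNA", "protein-IP",
                      "enrichment", "other")

#' Construct a source table of per-study gene entries
#'
#' A `source_table` holds the raw rows of one published gene table before
#' significance filtering: one gene token per row with optional raw and
#' adjusted P-values.
#'
#' @param source_id unique identifier of the originating table.
#' @param gene character vector of gene tokens.
#' @param p,p_adj numeric vectors in \[0,1\] or `NA` where absent.
#' @param publication_ref free-text reference.
#' @param category one of `"mRNA"`, `"smallRNA"`, `"totalRNA"`,
#'   `"protein-IP"`, `"enrichment"`, `"other"`.
#' @return an object of class `source_table`.
#' @export
source_table <- function(source_id, gene, p = NA_real_, p_adj = NA_real_,
                         publication_ref = "", category = "other") {
  category <- match.arg(category, VALID_CATEGORIES)
  stopifnot(is.character(gene))
  n <- length(gene)
  p <- rep_len(as.numeric(p), n)
  p_adj <- rep_len(as.numeric(p_adj), n)
  bad <- function(x) any(!is.na(x) & (x < 0 | x > 1))
  if (bad(p) || bad(p_adj))
    stop("p and p_adj must lie in [0,1] when present")
  structure(
    list(source_id = as.character(source_id),
         publication_ref = publication_ref,
         category = category,
         rows = data.frame(gene = gene, p = p, p_adj = p_adj,
                           stringsAsFactors = FALSE)),
    class = "source_table")
}

#' @export
print.source_table <- function(x, ...) {
  cat(sprintf("<source_table> %s (%s): %d rows\n",
              x$source_id, x$category, nrow(x$rows)))
  invisible(x)
}

#' Parse a delimited per-study gene table
#'
#' Reads one delimited text file into a [source_table()]. The `schema` names
#' which columns carry the gene token and the optional significance values;
#' unparseable P-values become `NA` (absent) rather than dropping the row.
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param schema list with `$gene` (required column name) and optional
#'   `$p`, `$p_adj` column names.
#' @param source_id identifier for the table; defaults to the file name.
#' @param sep field separator (default tab).
#' @inheritParams source_table
#' @return a `source_table`.
#' @export
parse_gene_table <- function(path, schema, source_id = basename(path),
                             publication_ref = "", category = "other",
                             sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  schema <- list(gene = schema[["gene"]], p = schema[["p"]],
                 p_adj = schema[["p_adj"]])  # exact names; no partial match
  if (is.null(schema$gene)) stop("schema must name a gene column")
  tab <- tryCatch(
    read.delim(path, sep = sep, stringsAsFactors = FALSE,
               check.names = FALSE),
    error = function(e) stop("cannot read ", path, ": ", conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty table: ", path)
  for (col in c(schema$gene, schema$p, schema$p_adj)) {
    if (!col %in% names(tab))
      stop("column '", col, "' not found in ", path)
  }
  getnum <- function(col) {
    if (is.null(col)) return(NA_real_)
    suppressWarnings(as.numeric(tab[[col]]))
  }
  source_table(source_id = source_id,
               gene = as.character(tab[[schema$gene]]),
               p = getnum(schema$p), p_adj = getnum(schema$p_adj),
               publication_ref = publication_ref, category = category)
}

#' Construct a gene list
#'
#' A `gene_list` is one study-derived list after filtering: a set of
#' canonical gene identifiers with provenance. `empty` flags lists whose
#' every row failed the significance filter; such lists are excluded from
#' downstream scoring.
#'
#' @param list_id,source_id identifiers.
#' @param genes character vector; duplicates collapse.
#' @param category table category (see [source_table()]).
#' @return an object of class `gene_list` with fields `genes` (sorted unique
#'   set) and `size` (`T_i`).
#' @export
gene_list <- function(list_id, genes, source_id = list_id,
                      category = "other") {
  genes <- sort(unique(as.character(genes)))
  genes <- genes[nzchar(genes)]
  structure(
    list(list_id = as.character(list_id),
         source_id = as.character(source_id),
         category = match.arg(category, VALID_CATEGORIES),
         genes = genes, size = length(genes), empty = length(genes) == 0L),
    class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> %s: %d genes%s\n", x$list_id, x$size,
              if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}

#' Apply the significance filter to a source table
#'
#' A row is retained iff its adjusted P-value (preferred when present) or
#' raw P-value is below `alpha`; rows carrying neither value are retained,
#' mirroring a filter applied only "when such values were available".
#'
#' @param table a [source_table()].
#' @param alpha significance threshold in (0,1); default 0.05.
#' @param prefer `"p_adj"` (default) or `"p"`: which value governs when both
#'   are present.
#' @return a [gene_list()]; possibly flagged empty.
#' @export
filter_significant <- function(table, alpha = 0.05, prefer = c("p_adj", "p")) {
  stopifnot(inherits(table, "source_table"), alpha > 0, alpha < 1)
  prefer <- match.arg(prefer)
  r <- table$rows
  primary <- if (prefer == "p_adj") r$p_adj else r$p
  secondary <- if (prefer == "p_adj") r$p else r$p_adj
  val <- ifelse(!is.na(primary), primary, secondary)
  keep <- is.na(val) | val < alpha
  gene_list(list_id = table$source_id, genes = r$gene[keep],
            source_id = table$source_id, category = table$category)
}

#' Standardize gene identifiers via an alias map
#'
#' Replaces every token by its canonical identifier. The map is a named
#' character vector (`names` = tokens, values = canonical ids); tokens not
#' in the map are handled per `policy`. The set is re-deduplicated after
#' mapping (two aliases of one gene collapse).
#'
#' @param list a [gene_list()].
#' @param aliases named character vector, token -> canonical id.
#' @param policy `"keep"` (keep tokens verbatim), `"drop"`, or `"error"`.
#' @return the mapped `gene_list`, with attribute `"unresolved"` listing
#'   tokens absent from the map.
#' @export
standardize_names <- function(list, aliases,
                              policy = c("keep", "drop", "error")) {
  stopifnot(inherits(list, "gene_list"))
  policy <- match.arg(policy)
  if (length(aliases) && anyDuplicated(names(aliases)))
    stop("alias map must be a function: duplicated tokens found")
  hit <- list$genes %in% names(aliases)
  unresolved <- list$genes[!hit]
  if (policy == "error" && length(unresolved))
    stop("unresolved gene tokens: ", paste(unresolved, collapse = ", "))
  mapped <- list$genes
  mapped[hit] <- unname(aliases[mapped[hit]])
  if (policy == "drop") mapped <- mapped[hit]
  out <- gene_list(list$list_id, mapped, list$source_id, list$category)
  attr(out, "unresolved") <- unresolved
  out
}

#' Write / read a collection of gene lists as canonical TSV
#'
#' The canonical format is one row per (list, gene) with columns
#' `list_id`, `source_id`, `category`, `gene`. A JSON manifest summarizing
#' the collection can be written alongside.
#'
#' @param lists a list of [gene_list()] objects.
#' @param path output TSV path.
#' @param manifest optional path for a JSON collection manifest.
#' @return `path`, invisibly.
#' @export
write_gene_lists <- function(lists, path, manifest = NULL) {
  rows <- do.call(rbind, lapply(lists, function(l) {
    if (l$empty) return(NULL)
    data.frame(list_id = l$list_id, source_id = l$source_id,
               category = l$category, gene = l$genes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(list_id = character(), source_id = character(),
                       category = character(), gene = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest)) {
    info <- list(
      n_lists = length(lists),
      n_empty = sum(vapply(lists, function(l) l$empty, logical(1))),
      sizes = setNames(lapply(lists, function(l) l$size),
                       vapply(lists, function(l) l$list_id, character(1))))
    jsonlite::write_json(info, manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_gene_lists
#' @export
read_gene_lists <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("list_id", "source_id", "category", "gene") %in% names(tab)))
    stop("not a canonical gene-list TSV: ", path)
  lapply(split(tab, factor(tab$list_id, levels = unique(tab$list_id))),
         function(d) gene_list(d$list_id[1], d$gene, d$source_id[1],
                               d$category[1]))
}
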