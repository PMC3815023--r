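#' Read a gene coordinate table from BED or GFF3
#'
#' BED input is the 6-column form (`chrom, start, end, name, score, strand`),
#' already 0-based half-open. GFF3 input (via rtracklayer) is 1-based closed
#' and is converted; rows of type `gene` are kept and the gene id is taken
#' from the given attribute (falling back to `ID`).
#'
#' @param path File path.
#' @param format `"bed"` or `"gff3"`.
#' @param id_attribute GFF3 attribute holding the gene id.
#' @return A [gene_table()].
#' @export
read_gene_table <- function(path, format = c("bed", "gff3"),
                            id_attribute = "ID") {
  format <- match.arg(format)
  if (format == "bed") {
    raw <- readr::read_tsv(path, col_names = c("chromosome", "start", "end",
                                               "gene_id", "score", "strand"),
                           col_types = "ciiccc", progress = FALSE)
    bad <- which(!raw$strand %in% c("+", "-"))
    if (length(bad) > 0L) {
      abort(sprintf("line %d: strand must be '+' or '-', got '%s'.",
                    bad[1], raw$strand[bad[1]]))
    }
    if (anyNA(raw$start) || anyNA(raw$end)) {
      abort(sprintf("line %d: malformed coordinates.",
                    which(is.na(raw$start) | is.na(raw$end))[1]))
    }
    return(gene_table(raw[, c("gene_id", "chromosome", "strand", "start", "end")]))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    md <- md[md$type == "gene", ]
  }
  id <- md[[id_attribute]] %||% md[["ID"]]
  if (is.null(id)) {
    abort(sprintf("GFF3 attribute `%s` not found.", id_attribute))
  }
  if (!all(md$strand %in% c("+", "-"))) {
    abort("GFF3 rows must carry '+' or '-' strands.")
  }
  gene_table(tibble(gene_id = as.character(id),
                    chromosome = as.character(md$seqnames),
                    strand = as.character(md$strand),
                    start = md$start - 1L,   # 1-based closed -> 0-based half-open
                    end = md$end))
}

#' Write a gene table as 6-column BED
#'
#' @param genes A [gene_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  genes <- gene_table(genes)
  readr::write_tsv(tibble(chromosome = genes$chromosome,
                          start = genes$start, end = genes$end,
                          gene_id = genes$gene_id, score = ".",
                          strand = genes$strand),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description (the source label), then member gene
#' ids, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()`: a collection tibble; `write_gmt()`: the path,
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  as_collection(tibble(
    set_name = vapply(parts, `[`, character(1), 1L),
    source = vapply(parts, `[`, character(1), 2L),
    genes = lapply(parts, function(p) p[-(1:2)])))
}

#' @rdname read_gmt
#' @param collection Collection tibble.
#' @export
write_gmt <- function(collection, path) {
  collection <- as_collection(collection)
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_name[i], collection$source[i],
            collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a minimal OBO ontology subset
#'
#' Only the fields this package uses are carried: `id`, `name`, `namespace`
#' and `is_a` links.
#'
#' @param path File path.
#' @return `read_obo()`: a [ontology()] object; `write_obo()`: the path,
#'   invisibly.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) {
    abort("no [Term] stanzas found.")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  terms <- list()
  parents <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), block,
                                                value = TRUE))
      if (length(v) == 0L) NA_character_ else v[1]
    }
    id <- get1("id")
    is_a <- sub("^is_a: ", "", grep("^is_a: ", block, value = TRUE))
    is_a <- sub(" !.*$", "", is_a)
    terms[[k]] <- tibble(term_id = id, name = get1("name"),
                         namespace = get1("namespace"))
    parents[[id]] <- is_a
  }
  ontology(bind_rows(terms), parents)
}

#' @rdname read_obo
#' @param onto A [ontology()] object.
#' @export
write_obo <- function(onto, path) {
  blocks <- vapply(seq_len(nrow(onto$terms)), function(i) {
    id <- onto$terms$term_id[i]
    pp <- onto$parents[[id]]
    paste(c("[Term]",
            paste0("id: ", id),
            paste0("name: ", onto$terms$name[i]),
            paste0("namespace: ", onto$terms$namespace[i]),
            if (length(pp) > 0) paste0("is_a: ", pp),
            ""),
          collapse = "\n")
  }, character(1))
  writeLines(c("format-version: 1.2", "", blocks), path)
  invisible(path)
}

#' Read and write annotation tables
#'
#' Three-column TSV: `gene_id`, `term_id`, `evidence`.
#'
#' @param path File path.
#' @return `read_annotations()`: an annotation tibble; the writer returns
#'   the path, invisibly.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_types = "ccc", progress = FALSE)
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations[, c("gene_id", "term_id", "evidence")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read and write expression matrices with a sample sheet
#'
#' The matrix is a TSV with a `gene_id` column; the sample sheet is a
#' sidecar TSV (`sample_id`, `group`, optional `tissue`) at
#' `<path>.samples.tsv` unless given.
#'
#' @param path Matrix file path.
#' @param samples_path Optional sample-sheet path.
#' @return `read_expression()`: a [expression_data()]; the writer returns
#'   the path, invisibly.
#' @export
read_expression <- function(path, samples_path = NULL) {
  samples_path <- samples_path %||% paste0(path, ".samples.tsv")
  mat <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  samples <- readr::read_tsv(samples_path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  values <- as.matrix(mat[, -1])
  rownames(values) <- mat$gene_id
  expression_data(values, samples)
}

#' @rdname read_expression
#' @param expr A [expression_data()] object.
#' @export
write_expression <- function(expr, path, samples_path = NULL) {
  samples_path <- samples_path %||% paste0(path, ".samples.tsv")
  tbl <- as_tibble(round(expr$values, 6), rownames = "gene_id")
  readr::write_tsv(tbl, path, progress = FALSE)
  readr::write_tsv(expr$samples, samples_path, progress = FALSE)
  invisible(path)
}

#' Write a set network as SIF
#'
#' One edge per line: `set_a <relation> set_b`, the relation being the map
#' kind.
#'
#' @param network A [build_set_network()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network_sif <- function(network, path) {
  lines <- sprintf("%s\t%s\t%s", network$edges$set_a, network$map_kind,
                   network$edges$set_b)
  writeLines(lines, path)
  invisible(path)
}

#' Convert a set network to igraph / GraphML
#'
#' `as_igraph()` carries node sizes and the edge attributes (`weight`,
#' `n_bridging`, `overlap_rate`, `interaction_rate`); `write_network_graphml()`
#' serialises that graph.
#'
#' @param network A [build_set_network()] object.
#' @return An igraph object.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("set_a", "set_b", "weight", "n_bridging",
                      "overlap_rate", "interaction_rate")],
    directed = FALSE,
    vertices = network$nodes[, c("set_name", "size")])
  g
}

#' @rdname as_igraph
#' @param path Output path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write pair truth lists and run manifests as JSON
#'
#' @param x A list or tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
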