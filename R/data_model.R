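#' @keywords internal
"_PACKAGE"

SITES <- c("tongue", "saliva")
CONDITIONS <- c("healthy", "halitosis")

#' Construct an OTU count table
#'
#' The central container of the pipeline: an integer count matrix with OTUs
#' as rows and samples as columns, plus an optional taxonomy label per OTU.
#'
#' @param counts integer matrix, OTUs x samples, with unique rownames
#'   (OTU ids) and colnames (sample ids); all entries non-negative.
#' @param taxonomy optional character vector of lineage strings, one per OTU
#'   (named by OTU id or in row order). Treated as opaque labels.
#' @return an object of class `otu_table` with elements `counts` and
#'   `taxonomy`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU ids as rownames and sample ids as colnames")
  .check_unique(rownames(counts), "OTU id")
  .check_unique(colnames(counts), "sample id")
  if (any(is.na(counts)))
    stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) {
      if (!all(rownames(counts) %in% names(taxonomy)))
        stop("taxonomy names do not cover all OTU ids")
      taxonomy <- taxonomy[rownames(counts)]
    } else if (length(taxonomy) != nrow(counts)) {
      stop("taxonomy length does not match number of OTUs")
    } else {
      names(taxonomy) <- rownames(counts)
    }
    taxonomy <- as.character(taxonomy)
    names(taxonomy) <- rownames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

.check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup))
    stop(sprintf("duplicate %s: %s", what, paste(dup, collapse = ", ")))
  invisible(TRUE)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%s taxonomy)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "with"))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read an OTU table from a tab-separated file
#'
#' Expects a header row whose first cell is `otu_id` followed by sample ids,
#' one row per OTU with integer counts, and an optional trailing `taxonomy`
#' column.
#'
#' @param path file path.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L || names(df)[1L] != "otu_id")
    stop("expected header starting with 'otu_id' followed by sample ids")
  tax <- NULL
  if (names(df)[ncol(df)] == "taxonomy") {
    tax <- as.character(df[[ncol(df)]])
    df <- df[, -ncol(df), drop = FALSE]
  }
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cells present")
  rownames(m) <- ids
  if (!is.null(tax)) names(tax) <- ids
  otu_table(m, taxonomy = tax)
}

#' Write an OTU table to a tab-separated file
#'
#' Canonical serialization: `otu_id`, sample columns, then `taxonomy` when
#' present. Round-trips losslessly through [read_otu_table()].
#'
#' @param x an [otu_table()].
#' @param path output path.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total so columns sum to one.
#'
#' @param table an [otu_table()] or a numeric count matrix (OTUs x samples).
#' @return numeric matrix of relative abundances with the same dimnames.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    bad <- colnames(m)[tot <= 0]
    stop(sprintf("all-zero sample column(s): %s", paste(bad, collapse = ", ")))
  }
  sweep(m, 2L, tot, "/")
}

#' Construct sample metadata
#'
#' @param sample_id,subject_id character vectors.
#' @param site values in `"tongue"`/`"saliva"`.
#' @param condition values in `"healthy"`/`"halitosis"`.
#' @return data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, subject_id, site, condition) {
  df <- data.frame(sample_id = as.character(sample_id),
                   subject_id = as.character(subject_id),
                   site = as.character(site),
                   condition = as.character(condition),
                   stringsAsFactors = FALSE)
  .check_unique(df$sample_id, "sample id")
  if (!all(df$site %in% SITES))
    stop("site values must be 'tongue' or 'saliva'")
  if (!all(df$condition %in% CONDITIONS))
    stop("condition values must be 'healthy' or 'halitosis'")
  key <- paste(df$subject_id, df$site)
  .check_unique(key, "(subject, site) pair")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from a tab-separated file
#'
#' Columns: `sample_id`, `subject_id`, `site`, `condition`.
#'
#' @param path file path.
#' @return a [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "site", "condition")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  sample_metadata(df$sample_id, df$subject_id, df$site, df$condition)
}

#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check that metadata covers every sample of a table
#' @param table an [otu_table()].
#' @param meta a [sample_metadata()].
#' @keywords internal
#' @export
validate_metadata <- function(table, meta) {
  missing <- setdiff(colnames(table$counts), meta$sample_id)
  if (length(missing))
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a rooted phylogenetic tree from a newick file
#'
#' Thin wrapper over [ape::read.tree()]. Missing branch lengths default to
#' zero (with a warning), so unmeasured branches contribute nothing to
#' UniFrac. Internal node labels are preserved and never treated as leaves.
#'
#' @param path newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  off <- .newick_imbalance(txt)
  if (!is.na(off))
    stop(sprintf("unparseable newick: unbalanced parenthesis near character %d", off))
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("unparseable newick in ", path)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0))
    stop("negative branch length in tree")
  tr
}

# first character position where parenthesis nesting breaks, NA if balanced
.newick_imbalance <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  if (depth != 0L) return(length(chars))
  NA_integer_
}

#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct a two-library gene abundance table
#'
#' Holds pooled metagenomic gene counts for one site: one healthy and one
#' halitosis library, plus total library sizes used for normalization.
#'
#' @param counts integer matrix, genes x 2, colnames `healthy`, `halitosis`.
#' @param library_sizes named numeric length 2 (total mapped counts per
#'   library); defaults to the column sums.
#' @return object of class `gene_table`.
#' @export
gene_table <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (!identical(colnames(counts), CONDITIONS))
    stop("counts must have exactly the columns 'healthy', 'halitosis'")
  .check_unique(rownames(counts), "gene id")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("gene counts must be non-negative integers")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- library_sizes[CONDITIONS]
  if (anyNA(library_sizes) || any(library_sizes <= 0))
    stop("library_sizes must be positive and named healthy/halitosis")
  if (any(library_sizes < colSums(counts)))
    stop("library_sizes smaller than column sums")
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "gene_table")
}

#' Read a two-library gene table from a tab-separated file
#'
#' Columns: `gene_id`, `count_healthy`, `count_halitosis`.
#'
#' @param path file path.
#' @param library_sizes optional named totals; default column sums.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path, library_sizes = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "count_healthy", "count_halitosis")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  m <- cbind(healthy = df$count_healthy, halitosis = df$count_halitosis)
  rownames(m) <- df$gene_id
  gene_table(m, library_sizes = library_sizes)
}

#' @export
write_gene_table <- function(gt, path) {
  df <- data.frame(gene_id = rownames(gt$counts),
                   count_healthy = gt$counts[, "healthy"],
                   count_halitosis = gt$counts[, "halitosis"])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene families of the hydrogen-sulphide metabolic map
#'
#' Sulphate-reduction, reverse-transsulphuration and cysteine-transamination
#' gene families scored by the H2S pathway report.
#'
#' @return character vector of family names.
#' @export
h2s_families <- function() {
  c("cysNC", "cysN", "cysD", "cysC", "cysH", "cysJ", "cysI", "aprA", "sir",
    "cbs", "mccB", "aspB", "aspC", "yhdR", "sseA", "glpE", "cysM")
}

#' Bundle gene-to-KO and gene-to-pathway-family annotation maps
#'
#' Genes in a map that are absent from the gene table are dropped with a
#' warning.
#'
#' @param ko data.frame with columns `gene_id`, `category` (many-to-many).
#' @param family data.frame with columns `gene_id`, `family`; families must
#'   come from [h2s_families()].
#' @param genes optional character vector of known gene ids to validate
#'   against.
#' @return object of class `annotation_maps`.
#' @export
annotation_maps <- function(ko = NULL, family = NULL, genes = NULL) {
  tidy <- function(df, valcol) {
    if (is.null(df)) return(NULL)
    df <- data.frame(gene_id = as.character(df$gene_id),
                     value = as.character(df[[valcol]]),
                     stringsAsFactors = FALSE)
    names(df)[2L] <- valcol
    if (!is.null(genes)) {
      unknown <- setdiff(df$gene_id, genes)
      if (length(unknown)) {
        warning(sprintf("%d annotated gene(s) absent from the gene table; ignored",
                        length(unknown)))
        df <- df[df$gene_id %in% genes, , drop = FALSE]
      }
    }
    df
  }
  family <- tidy(family, "family")
  if (!is.null(family)) {
    bad <- setdiff(unique(family$family), h2s_families())
    if (length(bad))
      stop("unknown pathway family: ", paste(bad, collapse = ", "))
  }
  structure(list(ko = tidy(ko, "category"), family = family),
            class = "annotation_maps")
}

#' @export
read_annotation_map <- function(path, value_name = "category") {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation map needs two columns")
  names(df)[1:2] <- c("gene_id", value_name)
  df[, 1:2]
}
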