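# Readers and writers for the plain-text interchange formats: abundance TSV,
# edge-list TSV, connectome CSV, annotation TSV, OBO subset, Newick, GEXF,
# Circos link files. Every writer stamps a header comment with the package
# version (and config hash when available); readers skip '#' comments.

#' Read an abundance table
#'
#' Expects a TSV with columns `protein_id`, `n_unique_peptides`, then one
#' intensity column per run named `<REGION>_<k>`. Duplicate protein ids and
#' non-positive intensities are rejected with a message naming the offender.
#'
#' @param path file path.
#' @return An `abundance_tensor`.
#' @export
read_abundance <- function(path) {
  df <- read_tsv(path)
  need <- c("protein_id", "n_unique_peptides")
  if (!all(need %in% names(df)))
    stopf("'%s': missing required columns %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$protein_id))
    stopf("'%s': duplicate protein id '%s'", path,
          df$protein_id[duplicated(df$protein_id)][1])
  runs <- setdiff(names(df), need)
  m <- regmatches(runs, regexec("^(.*)_([0-9]+)$", runs))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stopf("'%s': run column '%s' does not match <REGION>_<k>", path,
          runs[bad][1])
  regs <- vapply(m, `[`, character(1), 2)
  reps <- as.integer(vapply(m, `[`, character(1), 3))
  regions <- unique(regs)
  K <- max(reps)
  if (!all(table(regs) == K) || !all(sort(unique(reps)) == seq_len(K)))
    stopf("'%s': incomplete run grid (every region needs replicates 1..%d)",
          path, K)
  P <- nrow(df)
  arr <- array(NA_real_, dim = c(P, length(regions), K),
               dimnames = list(df$protein_id, regions, paste0("B", seq_len(K))))
  for (j in seq_along(runs)) {
    v <- df[[runs[j]]]
    if (!is.numeric(v) || anyNA(v) || any(v <= 0)) {
      row <- which(!is.finite(v) | v <= 0)[1]
      stopf("'%s': non-positive intensity at protein '%s', column '%s'",
            path, df$protein_id[row %||% 1], runs[j])
    }
    arr[, regs[j], reps[j]] <- v
  }
  new_abundance_tensor(arr, setNames(df$n_unique_peptides, df$protein_id))
}

#' Write an abundance tensor as a run-column TSV
#' @param tensor an `abundance_tensor`.
#' @param path file path.
#' @param config optional configuration echoed into the header hash.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(tensor, path, config = NULL) {
  write_tsv(tensor_to_frame(tensor), path, config = config)
}

#' Read a two-column PPI edge list (TSV: protein_a, protein_b)
#' @param path file path.
#' @return data.frame with character columns `protein_a`, `protein_b`.
#' @export
read_edges <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (!all(c("protein_a", "protein_b") %in% names(df)))
    stopf("'%s': expected columns protein_a, protein_b", path)
  df[c("protein_a", "protein_b")]
}

#' Write / read a square region-by-region connectome matrix (CSV)
#' @param m named square numeric matrix.
#' @param path file path.
#' @return `path` (write) or a named matrix (read).
#' @export
write_connectome <- function(m, path) {
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header(), con)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    stopf("'%s': connectome matrix must be square with matching labels", path)
  m
}

#' Read / write protein-to-term annotations (TSV: protein_id, term_id)
#' @param path file path.
#' @param annotations data.frame with `protein_id`, `term_id`.
#' @return data.frame (read) or `path` (write).
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (!all(c("protein_id", "term_id") %in% names(df)))
    stopf("'%s': expected columns protein_id, term_id", path)
  df[c("protein_id", "term_id")]
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  write_tsv(annotations, path)
}

#' Export an hclust dendrogram in Newick format
#' @param hc an `hclust` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export a weighted, partitioned graph as GEXF
#'
#' Minimal GEXF 1.2 with a `community` node attribute and per-region edge
#' weight attributes.
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame with `protein_a`, `protein_b`.
#' @param path file path.
#' @param membership optional named community vector.
#' @param weights optional numeric matrix (one row per edge, one column per
#'   region) of edge weights.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(nodes, edges, path, membership = NULL, weights = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <!-- %s -->', esc(file_header()))
  w('  <graph defaultedgetype="undirected">')
  w('    <attributes class="node">')
  w('      <attribute id="community" title="community" type="integer"/>')
  w('    </attributes>')
  if (!is.null(weights)) {
    w('    <attributes class="edge">')
    for (j in seq_len(ncol(weights)))
      w('      <attribute id="w_%s" title="weight_%s" type="double"/>',
        esc(colnames(weights)[j]), esc(colnames(weights)[j]))
    w('    </attributes>')
  }
  w('    <nodes>')
  for (n in nodes) {
    if (!is.null(membership))
      w('      <node id="%s" label="%s"><attvalues><attvalue for="community" value="%d"/></attvalues></node>',
        esc(n), esc(n), as.integer(membership[[n]]))
    else w('      <node id="%s" label="%s"/>', esc(n), esc(n))
  }
  w('    </nodes>')
  w('    <edges>')
  for (i in seq_len(nrow(edges))) {
    if (!is.null(weights)) {
      av <- paste(sprintf('<attvalue for="w_%s" value="%.10g"/>',
                          esc(colnames(weights)), weights[i, ]),
                  collapse = "")
      w('      <edge id="%d" source="%s" target="%s"><attvalues>%s</attvalues></edge>',
        i, esc(edges$protein_a[i]), esc(edges$protein_b[i]), av)
    } else {
      w('      <edge id="%d" source="%s" target="%s"/>', i,
        esc(edges$protein_a[i]), esc(edges$protein_b[i]))
    }
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}

#' Write Circos karyotype and link files for region-module links
#'
#' Regions become Circos "chromosomes" of unit length 1000; each link row
#' spans a band proportional to its width at both region ends and is colored
#' by module.
#'
#' @param links a link table from [circos_links()].
#' @param regions character vector of region names.
#' @param dir output directory.
#' @return Invisible character vector of the two file paths.
#' @export
write_circos <- function(links, regions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kpath <- file.path(dir, "karyotype.txt")
  lpath <- file.path(dir, "links.txt")
  palette <- c("red", "blue", "green", "orange", "purple", "yellow",
               "grey", "black")
  writeLines(c(file_header(),
               sprintf("chr - %s %s 0 1000 chr%d", regions, regions,
                       seq_along(regions))), kpath)
  off <- setNames(rep(0, length(regions)), regions)
  out <- character(0)
  for (i in seq_len(nrow(links))) {
    a <- links$region_a[i]; b <- links$region_b[i]
    wa <- round(1000 * links$width[i])
    col <- palette[(links$module[i] - 1) %% length(palette) + 1]
    out <- c(out, sprintf("%s %d %d %s %d %d color=%s", a, off[[a]],
                          off[[a]] + wa, b, off[[b]], off[[b]] + wa, col))
    off[[a]] <- off[[a]] + wa
    off[[b]] <- off[[b]] + wa
  }
  writeLines(c(file_header(), out), lpath)
  invisible(c(kpath, lpath))
}
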