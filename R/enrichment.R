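# Ontology DAG handling and over-representation analysis: annotation
# propagation (true-path rule), classic one-sided hypergeometric (Fisher)
# tests, and the topology-based elimination Fisher algorithm in which genes
# of significantly enriched child terms are removed from their ancestors
# before those are tested.

#' Construct an ontology DAG
#'
#' @param terms data.frame with columns `id`, `name`.
#' @param parents named list: term id -> character vector of is-a parents
#'   (empty for roots). Acyclicity is verified by topological sort.
#' @return A list of class `psd_ontology`: `terms`, `parents`, `children`,
#'   `roots`, `levels` (longest path to a root), `order` (topological,
#'   leaves-first within level, lexicographic ties).
#' @export
new_ontology <- function(terms, parents) {
  stopifnot(all(c("id", "name") %in% names(terms)))
  ids <- terms$id
  if (!setequal(names(parents), ids))
    stopf("parents list must cover exactly the term ids")
  parents <- parents[ids]
  bad <- setdiff(unlist(parents), ids)
  if (length(bad)) stopf("unknown parent term '%s'", bad[1])
  # Kahn topological sort over child -> parent edges; also yields levels
  # (longest path from a root).
  roots <- ids[vapply(parents, length, integer(1)) == 0]
  if (!length(roots)) stopf("ontology has no root (cycle?)")
  children <- setNames(vector("list", length(ids)), ids)
  for (t in ids) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)
  indeg <- vapply(parents, length, integer(1))      # unresolved parents
  level <- setNames(rep(0L, length(ids)), ids)
  queue <- roots
  seen <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    seen <- c(seen, t)
    for (ch in children[[t]]) {
      level[ch] <- max(level[ch], level[t] + 1L)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(seen) != length(ids)) {
    cyc <- setdiff(ids, seen)
    stopf("ontology contains a cycle involving term '%s'", cyc[1])
  }
  ord <- ids[order(-level[ids], ids)]               # deepest first
  structure(list(terms = terms, parents = parents, children = children,
                 roots = roots, levels = level, order = ord),
            class = "psd_ontology")
}

#' @export
print.psd_ontology <- function(x, ...) {
  cat(sprintf("psd_ontology: %d terms, %d root(s), max depth %d\n",
              nrow(x$terms), length(x$roots), max(x$levels)))
  invisible(x)
}

#' All is-a ancestors of a term (excluding itself)
#' @param ontology a `psd_ontology`.
#' @param term term id.
#' @return Character vector of ancestor ids.
#' @export
term_ancestors <- function(ontology, term) {
  out <- character(0)
  queue <- ontology$parents[[term]]
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    if (!t %in% out) {
      out <- c(out, t)
      queue <- c(queue, ontology$parents[[t]])
    }
  }
  sort(out)
}

#' Propagate annotations up the DAG (true-path rule)
#'
#' Closes each protein's direct annotations over all is-a ancestors, so a
#' protein annotated to a term is annotated to every ancestor of that term.
#' Idempotent.
#'
#' @param ontology a `psd_ontology`.
#' @param annotations data.frame `protein_id`, `term_id` (direct).
#' @return A list of class `psd_annotations`: `direct` and `propagated`
#'   (both data.frames), and `term_proteins` (named list term -> proteins,
#'   propagated).
#' @export
propagate_annotations <- function(ontology, annotations) {
  stopifnot(inherits(ontology, "psd_ontology"))
  bad <- setdiff(annotations$term_id, ontology$terms$id)
  if (length(bad)) stopf("annotation to unknown term '%s'", bad[1])
  anc <- lapply(setNames(nm = ontology$terms$id),
                function(t) c(t, term_ancestors(ontology, t)))
  prop <- if (nrow(annotations) == 0) {
    data.frame(protein_id = character(), term_id = character(),
               stringsAsFactors = FALSE)
  } else {
    unique(do.call(rbind, lapply(seq_len(nrow(annotations)),
      function(i) data.frame(protein_id = annotations$protein_id[i],
                             term_id = anc[[annotations$term_id[i]]],
                             stringsAsFactors = FALSE))))
  }
  prop <- prop[order(prop$term_id, prop$protein_id), ]
  rownames(prop) <- NULL
  structure(list(direct = annotations, propagated = prop,
                 term_proteins = split(prop$protein_id, prop$term_id)),
            class = "psd_annotations")
}

#' Classic one-sided hypergeometric (Fisher) enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` of observing at least the seen overlap
#' between the study set and the term's annotated proteins, drawing
#' `n = |study|` from a universe of size `N` containing `K` annotated
#' proteins.
#'
#' @param study character vector (subset of `universe`).
#' @param universe character vector of protein ids.
#' @param term_proteins proteins annotated (after propagation) to the term.
#' @return p-value in (0, 1]; `K = 0` gives 1.
#' @export
classic_fisher <- function(study, universe, term_proteins) {
  if (!all(study %in% universe)) stopf("study set must lie in the universe")
  N <- length(unique(universe)); n <- length(unique(study))
  tp <- intersect(term_proteins, universe)
  K <- length(tp)
  if (K == 0) return(1)
  k <- length(intersect(study, tp))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Topology-based elimination Fisher enrichment over the DAG
#'
#' Terms are tested bottom-up (children strictly before parents, deepest
#' level first, lexicographic term-id order within a level). When a term's
#' elimination p-value falls below `alpha_elim`, the proteins currently
#' annotated to it are removed from all of its ancestors' annotation sets
#' before those ancestors are tested, so a parent is not called enriched
#' merely because a child carries the signal. Classic p-values (no
#' elimination) are reported alongside.
#'
#' @param ontology a `psd_ontology`.
#' @param annotations a `psd_annotations` from [propagate_annotations()] (or
#'   a direct-annotation data.frame, propagated on the fly).
#' @param study character vector of study proteins.
#' @param universe character vector of background proteins (contains study).
#' @param alpha_elim elimination threshold (default 0.01).
#' @return data.frame `term_id`, `name`, `level`, `k`, `n`, `K`, `N`,
#'   `p_classic`, `p_elim`, `eliminated` (did this term trigger removal),
#'   sorted by `p_elim`.
#' @export
elim_fisher <- function(ontology, annotations, study, universe,
                        alpha_elim = 0.01) {
  stopifnot(inherits(ontology, "psd_ontology"))
  if (!inherits(annotations, "psd_annotations"))
    annotations <- propagate_annotations(ontology, annotations)
  if (!all(study %in% universe)) stopf("study set must lie in the universe")
  study <- unique(study); universe <- unique(universe)
  N <- length(universe); n <- length(study)
  sets <- lapply(ontology$terms$id, function(t)
    intersect(annotations$term_proteins[[t]], universe))
  names(sets) <- ontology$terms$id
  cur <- sets
  rows <- list()
  for (t in ontology$order) {
    K0 <- length(sets[[t]])
    k0 <- length(intersect(study, sets[[t]]))
    p_classic <- if (K0 == 0) 1 else
      phyper(k0 - 1, K0, N - K0, n, lower.tail = FALSE)
    K <- length(cur[[t]])
    k <- length(intersect(study, cur[[t]]))
    p_elim <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    elim <- p_elim < alpha_elim
    if (elim) {
      drop <- cur[[t]]
      for (a in term_ancestors(ontology, t))
        cur[[a]] <- setdiff(cur[[a]], drop)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = t, level = unname(ontology$levels[t]),
      k = k, n = n, K = K, N = N, p_classic = p_classic, p_elim = p_elim,
      eliminated = elim, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$name <- ontology$terms$name[match(out$term_id, ontology$terms$id)]
  out <- out[order(out$p_elim, out$term_id),
             c("term_id", "name", "level", "k", "n", "K", "N",
               "p_classic", "p_elim", "eliminated")]
  rownames(out) <- NULL
  out
}

#' Enrichment of every cluster (or module) of a partition
#'
#' Runs [elim_fisher()] with each cluster as the study set against a common
#' universe, BH-adjusting the elimination p-values across terms within each
#' cluster.
#'
#' @param membership named cluster/module id per protein.
#' @param ontology a `psd_ontology`.
#' @param annotations a `psd_annotations` (or direct data.frame).
#' @param universe background set; default all proteins in `membership`.
#' @param alpha_elim elimination threshold.
#' @param min_size skip clusters smaller than this (default 3).
#' @return A long data.frame with a `cluster` column, per-term enrichment
#'   rows (`p_classic`, `p_elim`, `p_adj`), plus a `top_terms` attribute
#'   (best term per cluster).
#' @export
enrich_clusters <- function(membership, ontology, annotations,
                            universe = NULL, alpha_elim = 0.01,
                            min_size = 3) {
  if (is.null(universe)) universe <- names(membership)
  if (!inherits(annotations, "psd_annotations"))
    annotations <- propagate_annotations(ontology, annotations)
  out <- list()
  for (cl in sort(unique(membership))) {
    set <- intersect(names(membership)[membership == cl], universe)
    if (length(set) < min_size) next
    res <- elim_fisher(ontology, annotations, set, universe,
                       alpha_elim = alpha_elim)
    res$p_adj <- bh_adjust(res$p_elim)
    out[[length(out) + 1L]] <- cbind(data.frame(cluster = cl), res)
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  top <- do.call(rbind, lapply(split(res, res$cluster), function(df)
    df[which.min(df$p_elim), c("cluster", "term_id", "name", "p_elim",
                               "p_adj")]))
  attr(res, "top_terms") <- top
  res
}

#' Read / write an OBO-subset ontology file
#'
#' Supports the minimal stanza subset: `[Term]` blocks with `id`, `name` and
#' `is_a` lines.
#'
#' @param path file path.
#' @param ontology a `psd_ontology` (for writing).
#' @return A `psd_ontology` (read) or `path` (write).
#' @export
read_obo <- function(path) {
  lines <- trimws(readLines(path))
  ids <- character(0); nm <- character(0); parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      ids <<- c(ids, cur$id); nm <<- c(nm, cur$name %||% cur$id)
      parents[[cur$id]] <<- cur$isa
    }
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush()
      cur <- list(id = NA_character_, name = NULL, isa = character(0))
    } else if (!is.null(cur)) {
      if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
      else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
      else if (startsWith(ln, "is_a:")) {
        v <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        cur$isa <- c(cur$isa, v)
      }
    }
  }
  flush()
  new_ontology(data.frame(id = ids, name = nm, stringsAsFactors = FALSE),
               parents)
}

#' @rdname read_obo
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "psd_ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               sprintf("! %s", file_header()), ""), con)
  nm <- setNames(ontology$terms$name, ontology$terms$id)
  for (t in ontology$terms$id) {
    writeLines(c("[Term]", paste0("id: ", t), paste0("name: ", nm[[t]]),
                 sprintf("is_a: %s ! %s", ontology$parents[[t]],
                         nm[ontology$parents[[t]]]),
                 ""), con)
  }
  invisible(path)
}
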