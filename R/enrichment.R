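#' Read a GMT gene-set collection
#'
#' Tab-delimited gene-set format: one set per line as
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return Long tibble (set_id, description, gene_id); set ids unique, sets
#'   non-empty.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("GMT line with fewer than 3 fields: line ", which(bad)[1L], call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate gene-set ids in GMT", call. = FALSE)
  purrr::map_dfr(parts, function(p) {
    tibble::tibble(set_id = p[[1L]], description = p[[2L]],
                   gene_id = unique(p[-c(1L, 2L)]))
  })
}

gene_set <- function(sets, id) {
  g <- sets$gene_id[sets$set_id == id]
  if (length(g) == 0L) stop("unknown or empty gene set: ", id, call. = FALSE)
  unique(g)
}

#' Read a two-column annotated gene-pair list
#'
#' @param path Delimited file, two columns of gene ids per row.
#' @param delim Field delimiter.
#' @return Tibble (gene_a, gene_b) of unique unordered pairs with
#'   `gene_a < gene_b`; self-pairs are dropped.
#' @export
read_gene_pairs <- function(path, delim = "\t") {
  tb <- utils::read.table(path, header = FALSE, sep = delim, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tb) < 2L) stop("pair annotation needs two columns", call. = FALSE)
  a <- as.character(tb[[1L]]); b <- as.character(tb[[2L]])
  keep <- a != b
  tibble::tibble(gene_a = pmin(a[keep], b[keep]),
                 gene_b = pmax(a[keep], b[keep])) |>
    dplyr::distinct()
}

#' Read an ontology DAG as child-to-parent edges
#'
#' Accepts either a two-column delimited file (child id, parent id) or an
#' OBO-format file, from which `id:` and `is_a:` tags of `[Term]` stanzas are
#' extracted (obsolete terms skipped).
#'
#' @param path Path to the edge file.
#' @param delim Delimiter for the two-column format.
#' @return Tibble (child, parent).
#' @export
read_ontology <- function(path, delim = "\t") {
  first <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^\\[Term\\]", first)) || grepl("\\.obo$", path)) {
    lines <- readLines(path, warn = FALSE)
    term_starts <- grep("^\\[Term\\]", lines)
    out <- purrr::map_dfr(seq_along(term_starts), function(i) {
      from <- term_starts[i] + 1L
      to <- if (i < length(term_starts)) term_starts[i + 1L] - 1L else length(lines)
      block <- lines[from:to]
      block <- block[seq_len(max(0L, min(length(block), which(block == "")[1L] - 1L, na.rm = TRUE)))]
      if (any(grepl("^is_obsolete: true", block))) return(NULL)
      id <- sub("^id: *", "", grep("^id: ", block, value = TRUE)[1L])
      parents <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a: ", block, value = TRUE)))
      if (is.na(id) || length(parents) == 0L) return(NULL)
      tibble::tibble(child = id, parent = parents)
    })
    return(out)
  }
  tb <- utils::read.table(path, header = FALSE, sep = delim, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  tibble::tibble(child = as.character(tb[[1L]]), parent = as.character(tb[[2L]]))
}

#' Read gene-to-term annotations
#'
#' @param path Two-column delimited file (gene id, term id).
#' @param delim Field delimiter.
#' @return Tibble (gene_id, term_id), distinct rows.
#' @export
read_annotations <- function(path, delim = "\t") {
  tb <- utils::read.table(path, header = FALSE, sep = delim, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  tibble::tibble(gene_id = as.character(tb[[1L]]),
                 term_id = as.character(tb[[2L]])) |>
    dplyr::distinct()
}

#' Fraction of graph edges between annotated genes
#'
#' The percentage of edges whose endpoints are both annotated: by default,
#' both members of the union of all set members; with `same_set = TRUE`, both
#' members of at least one common set (the stricter reading).
#'
#' @param graph Edge tibble (`gene_a`, `gene_b`).
#' @param sets Gene-set collection (long tibble from [read_gmt()]).
#' @param same_set Require both endpoints in one common set (default FALSE).
#' @return Percentage in `[0, 100]`.
#' @export
annotated_edge_fraction <- function(graph, sets, same_set = FALSE) {
  if (nrow(graph) == 0L) stop("empty graph", call. = FALSE)
  if (!same_set) {
    ann <- unique(sets$gene_id)
    hit <- graph$gene_a %in% ann & graph$gene_b %in% ann
  } else {
    by_set <- split(sets$gene_id, sets$set_id)
    hit <- rep(FALSE, nrow(graph))
    for (g in by_set) {
      hit <- hit | (graph$gene_a %in% g & graph$gene_b %in% g)
    }
  }
  100 * mean(hit)
}

#' Fraction of graph edges present in a pair annotation
#'
#' @param graph Edge tibble (`gene_a`, `gene_b`).
#' @param pairs Annotated unordered pairs (tibble from [read_gene_pairs()]).
#' @return Percentage of edges found among the annotated pairs.
#' @export
annotated_pair_fraction <- function(graph, pairs) {
  if (nrow(graph) == 0L) stop("empty graph", call. = FALSE)
  ek <- pair_key(graph$gene_a, graph$gene_b)
  ak <- pair_key(pairs$gene_a, pairs$gene_b)
  100 * mean(ek %in% ak)
}

#' Within-pathway edge recovery along a sweep
#'
#' For each requested graph size, takes the most stringent sweep step whose
#' vertex count first reaches that size and counts the accepted edges with
#' both endpoints inside the pathway, along with the percentage of pathway
#' genes present in the graph.
#'
#' @param sweep An [stringency_sweep()] object.
#' @param sets Gene-set collection.
#' @param pathway_id Set id to score.
#' @param vertex_sizes Target vertex counts.
#' @return Tibble (target_vertices, step, n_vertices, n_edges_within,
#'   pct_pathway_genes).
#' @export
within_pathway_recovery <- function(sweep, sets, pathway_id, vertex_sizes) {
  genes <- gene_set(sets, pathway_id)
  if (length(genes) < 2L) stop("pathway needs at least 2 genes", call. = FALSE)
  purrr::map_dfr(vertex_sizes, function(sz) {
    step <- step_at_size(sweep, sz, "vertices")
    g <- graph_at(sweep, step)
    inside <- g$gene_a %in% genes & g$gene_b %in% genes
    tibble::tibble(
      target_vertices = sz,
      step = step,
      n_vertices = sweep$steps$n_vertices[step],
      n_edges_within = sum(inside),
      pct_pathway_genes = 100 * mean(genes %in% graph_vertices(g))
    )
  })
}

#' Permutation null for within-pathway recovery
#'
#' Builds randomly permuted models of a pathway -- random gene sets of the
#' same size whose mean expression levels mimic the pathway's -- and
#' recomputes the recovery curve for each, yielding a false-discovery
#' envelope. Genes are stratified into `match_bins` equal-frequency bins of
#' mean expression and each permutation draws, per bin, as many genes as the
#' pathway has there.
#'
#' @param x Expression tibble (the gene universe and its expression levels).
#' @param sweep An [stringency_sweep()] object built over `x`.
#' @param sets Gene-set collection.
#' @param pathway_id Set id whose null is wanted.
#' @param vertex_sizes Target vertex counts for the curve.
#' @param n_perm Number of permutations (default 100).
#' @param match_bins Number of mean-expression bins (default 10).
#' @param seed RNG seed (recorded in the output attributes).
#' @return Tibble (target_vertices, observed, null_mean, null_min, null_max)
#'   of class `ra_perm_null`, with the per-permutation curves in attribute
#'   `"null_curves"`.
#' @export
permuted_pathway_null <- function(x, sweep, sets, pathway_id, vertex_sizes,
                                  n_perm = 100L, match_bins = 10L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  m <- expr_values(x)
  means <- rowMeans(m)
  universe <- rownames(m)
  bin <- mi_bin(means, match_bins)          # equal-frequency strata
  genes <- intersect(gene_set(sets, pathway_id), universe)
  if (length(genes) < 2L) stop("pathway has fewer than 2 detected genes", call. = FALSE)
  need <- table(factor(bin[match(genes, universe)], levels = seq_len(match_bins)))
  avail <- table(factor(bin, levels = seq_len(match_bins)))
  short <- which(as.integer(need) > as.integer(avail))
  if (length(short) > 0L) {
    stop("expression bin ", short[1L], " has too few candidate genes", call. = FALSE)
  }

  steps <- vapply(vertex_sizes, function(sz) step_at_size(sweep, sz, "vertices"), 1L)
  edge_sets <- lapply(steps, function(s) {
    g <- sweep$pairs[sweep$pairs$step_first <= s, ]
    cbind(g$gene_a, g$gene_b)
  })
  count_within <- function(set) {
    vapply(edge_sets, function(e) {
      sum(e[, 1L] %in% set & e[, 2L] %in% set)
    }, 1L)
  }
  observed <- count_within(genes)

  set.seed(seed)
  by_bin <- split(universe, bin)
  null <- matrix(0L, nrow = n_perm, ncol = length(vertex_sizes))
  for (p in seq_len(n_perm)) {
    draw <- unlist(lapply(seq_len(match_bins), function(k) {
      nk <- as.integer(need[k])
      if (nk == 0L) character(0) else sample(by_bin[[as.character(k)]], nk)
    }), use.names = FALSE)
    null[p, ] <- count_within(draw)
  }

  out <- tibble::tibble(
    target_vertices = vertex_sizes,
    observed = observed,
    null_mean = colMeans(null),
    null_min = apply(null, 2L, min),
    null_max = apply(null, 2L, max)
  )
  attr(out, "null_curves") <- null
  attr(out, "seed") <- seed
  attr(out, "pathway_id") <- pathway_id
  class(out) <- c("ra_perm_null", class(out))
  out
}

#' Aggregate ontology terms to a minimum detected-gene count
#'
#' Annotations are first propagated up the DAG, so a term's detected gene set
#' includes those of its descendants. Terms whose detected count reaches
#' `min_size` become aggregation anchors; every smaller term is merged into
#' its closest anchor ancestor (minimum edge distance; ties broken by fewest
#' detected genes, then lexicographic id). Terms with no qualifying ancestor
#' are merged into the root and flagged.
#'
#' @param dag Edge tibble (child, parent); must be acyclic.
#' @param annotations Tibble (gene_id, term_id) of direct annotations.
#' @param detected_genes Character vector of detected genes; only these count
#'   toward sizes and appear in the output sets.
#' @param min_size Minimum detected-gene count per aggregated category
#'   (default 200).
#' @return List of class `ra_ontology_agg` with `categories` (category_id,
#'   n_detected, at_root), `members` (category_id, term_id) and `genes`
#'   (set_id, gene_id) usable directly by [category_enrichment()].
#' @export
aggregate_ontology <- function(dag, annotations, detected_genes, min_size = 200L) {
  terms <- unique(c(dag$child, dag$parent, annotations$term_id))
  parents <- split(dag$parent, factor(dag$child, levels = terms))
  children <- split(dag$child, factor(dag$parent, levels = terms))

  # Kahn topological order (children before parents); detects cycles
  n_unprocessed_children <- vapply(children, length, 1L)
  queue <- terms[n_unprocessed_children == 0L]
  topo <- character(0)
  remaining <- n_unprocessed_children
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, t)
    for (p in parents[[t]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(topo) != length(terms)) stop("ontology contains a cycle", call. = FALSE)

  ann <- annotations[annotations$gene_id %in% detected_genes, ]
  direct <- split(ann$gene_id, factor(ann$term_id, levels = terms))
  genes_of <- stats::setNames(vector("list", length(terms)), terms)
  for (t in topo) {
    g <- direct[[t]]
    for (ch in children[[t]]) g <- c(g, genes_of[[ch]])
    genes_of[[t]] <- unique(g)
  }
  sizes <- vapply(genes_of, length, 1L)
  anchors <- terms[sizes >= min_size]
  roots <- terms[vapply(parents[terms], length, 1L) == 0L]

  assign_to <- character(length(terms)); names(assign_to) <- terms
  at_root <- logical(length(terms)); names(at_root) <- terms
  for (t in terms) {
    if (t %in% anchors) { assign_to[[t]] <- t; next }
    frontier <- parents[[t]]
    seen <- t
    found <- character(0)
    while (length(frontier) > 0L && length(found) == 0L) {
      frontier <- setdiff(unique(frontier), seen)
      found <- intersect(frontier, anchors)
      if (length(found) > 0L) break
      seen <- c(seen, frontier)
      frontier <- unlist(parents[frontier], use.names = FALSE)
    }
    if (length(found) > 0L) {
      found <- found[order(sizes[found], found)]
      assign_to[[t]] <- found[[1L]]
    } else {
      # no qualifying ancestor: merge into the reachable root
      all_anc <- character(0)
      frontier2 <- t
      repeat {
        ps <- setdiff(unique(unlist(parents[frontier2], use.names = FALSE)), all_anc)
        if (length(ps) == 0L) break
        all_anc <- c(all_anc, ps)
        frontier2 <- ps
      }
      rr <- intersect(all_anc, roots)
      if (length(rr) == 0L) rr <- t    # t itself is a root
      assign_to[[t]] <- sort(rr)[[1L]]
      at_root[[t]] <- TRUE
    }
  }

  members <- tibble::tibble(category_id = unname(assign_to), term_id = terms)
  cat_genes <- members |>
    dplyr::group_by(.data$category_id) |>
    dplyr::summarise(gene_id = list(unique(unlist(genes_of[.data$term_id]))),
                     .groups = "drop") |>
    tidyr::unnest("gene_id")
  categories <- cat_genes |>
    dplyr::group_by(.data$category_id) |>
    dplyr::summarise(n_detected = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(at_root = vapply(.data$category_id, function(cid) {
      any(at_root[members$term_id[members$category_id == cid]])
    }, TRUE))
  structure(
    list(categories = categories, members = members,
         genes = dplyr::rename(cat_genes, set_id = "category_id")),
    class = "ra_ontology_agg"
  )
}

#' Hypergeometric enrichment of categories in a gene selection
#'
#' One-sided hypergeometric tail test per category (the probability of
#' drawing at least the observed overlap when sampling the selection from the
#' background), Bonferroni-corrected over the tested categories.
#'
#' @param selection Character vector of selected genes (subset of
#'   `background`).
#' @param categories Long gene-set tibble (`set_id`, `gene_id`), e.g.
#'   [read_gmt()] output or the `genes` element of [aggregate_ontology()].
#' @param background Character vector: the gene universe.
#' @param alpha Corrected-p significance threshold (default 1e-4).
#' @return Tibble (category_id, overlap, category_size, selection_size,
#'   background_size, p_value, p_bonferroni, enriched) sorted by p.
#' @export
category_enrichment <- function(selection, categories, background, alpha = 1e-4) {
  selection <- unique(selection)
  background <- unique(background)
  if (!all(selection %in% background)) {
    stop("selection must be a subset of the background", call. = FALSE)
  }
  cats <- categories |>
    dplyr::filter(.data$gene_id %in% background) |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(genes = list(unique(.data$gene_id)), .groups = "drop")
  n_tests <- nrow(cats)
  N <- length(background); n <- length(selection)
  out <- purrr::map_dfr(seq_len(n_tests), function(i) {
    K <- length(cats$genes[[i]])
    k <- length(intersect(cats$genes[[i]], selection))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(category_id = cats$set_id[i], overlap = k,
                   category_size = K, selection_size = n,
                   background_size = N, p_value = p)
  })
  out |>
    dplyr::mutate(p_bonferroni = pmin(1, .data$p_value * n_tests),
                  enriched = .data$p_bonferroni <= alpha) |>
    dplyr::arrange(.data$p_value, .data$category_id)
}

#' Per-pathway expression-CV profiles and group comparisons
#'
#' For every gene of every pathway, the CV of its expression across samples;
#' optionally, with a pathway-to-group assignment, per-group means and
#' pairwise Welch two-sample t-tests on the gene-level CVs.
#'
#' @param x Expression tibble.
#' @param sets Gene-set collection.
#' @param groups Optional named vector or two-column data frame mapping
#'   `set_id` to a group label.
#' @param cv_ddof Degrees-of-freedom correction for the gene CV (default 1).
#' @return List with `profiles` (set_id, gene_id, cv), and when `groups` is
#'   given, `group_means` (group, mean_cv, n_genes) and `comparisons`
#'   (group_1, group_2, mean_1, mean_2, p_value).
#' @export
pathway_cv_profiles <- function(x, sets, groups = NULL, cv_ddof = 1L) {
  m <- expr_values(x)
  gene_cv <- apply(m, 1L, cv_of, ddof = cv_ddof)
  profiles <- sets |>
    dplyr::filter(.data$gene_id %in% rownames(m)) |>
    dplyr::distinct(.data$set_id, .data$gene_id) |>
    dplyr::mutate(cv = unname(gene_cv[.data$gene_id]))
  if (nrow(profiles) == 0L) stop("no pathway gene detected in the matrix", call. = FALSE)
  if (is.null(groups)) return(list(profiles = profiles))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2L]]), as.character(groups[[1L]]))
  }
  prof <- profiles |>
    dplyr::mutate(group = unname(groups[.data$set_id])) |>
    dplyr::filter(!is.na(.data$group))
  gm <- prof |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_cv = mean(.data$cv), n_genes = dplyr::n(), .groups = "drop")
  labs <- sort(unique(prof$group))
  comps <- purrr::map_dfr(utils::combn(labs, 2L, simplify = FALSE), function(pr) {
    x1 <- prof$cv[prof$group == pr[1L]]
    x2 <- prof$cv[prof$group == pr[2L]]
    tibble::tibble(group_1 = pr[1L], group_2 = pr[2L],
                   mean_1 = mean(x1), mean_2 = mean(x2),
                   p_value = stats::t.test(x1, x2)$p.value)
  })
  list(profiles = prof, group_means = gm, comparisons = comps)
}
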