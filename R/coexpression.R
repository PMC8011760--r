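# Lightweight weighted co-expression analysis: signed-absolute power
# adjacency, topological overlap, average-linkage module detection with a
# static tree cut, module eigengenes (first principal component), top-edge
# export, and hypergeometric term enrichment.

#' Signed-absolute power adjacency
#'
#' `a_ij = |pearson(i, j)|^beta`, unit diagonal. Zero-variance features are
#' excluded with a warning naming them.
#'
#' @param expr Matrix, features x samples (e.g. log2(cpm+1)).
#' @param beta Soft-threshold power (>= 1, default 6).
#' @return Symmetric features x features matrix with entries in \[0, 1\].
#' @export
coexpr_adjacency <- function(expr, beta = 6) {
  if (beta < 1) stop("beta must be >= 1")
  if (ncol(expr) < 3L) stop("need at least three samples")
  v <- apply(expr, 1L, var)
  if (any(v == 0)) {
    warning("excluding zero-variance features: ",
            paste(rownames(expr)[v == 0], collapse = ", "))
    expr <- expr[v > 0, , drop = FALSE]
  }
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i` the connectivity (row sum
#' minus diagonal). Diagonal is 1.
#'
#' @param adjacency Valid adjacency matrix from [coexpr_adjacency()].
#' @return Symmetric matrix of the same dimension.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-12)
    stop("adjacency must be square and symmetric")
  k <- rowSums(a) - diag(a)
  # l_ij = sum_{u != i,j} a_iu a_uj: subtract the u = i and u = j terms
  L <- a %*% a
  L <- L - sweep(a, 1L, diag(a), "*") - sweep(a, 2L, diag(a), "*")
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at `cut_height`; clusters smaller than `min_module_size` are pooled
#' into `"unassigned"`. Modules are labelled `M1, M2, ...` in decreasing
#' size order. On topological-overlap dissimilarities, tightly co-expressed
#' blocks sit well below 0.5 while unrelated features join near 0.9, so the
#' default cut of 0.7 separates planted structure without fragmenting it;
#' it is a tuning parameter and should be inspected per dataset.
#'
#' @param tom Topological-overlap matrix from [tom_similarity()].
#' @param min_module_size Minimum members per module (default 10).
#' @param cut_height Static cut height on `1 - TOM` (default 0.7).
#' @return List with `membership` (named character vector) and `modules`
#'   (named list of member id vectors, `unassigned` excluded).
#' @export
detect_modules <- function(tom, min_module_size = 10L, cut_height = 0.7) {
  d <- as.dist(1 - tom)
  cl <- if (nrow(tom) == 1L) setNames(1L, rownames(tom))
        else cutree(hclust(d, method = "average"), h = cut_height)
  names(cl) <- rownames(tom)
  sizes <- sort(table(cl), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_module_size]
  lab <- setNames(rep("unassigned", length(cl)), names(cl))
  for (i in seq_along(big))
    lab[cl == as.integer(big[i])] <- paste0("M", i)
  modules <- split(names(lab), lab)
  modules <- modules[names(modules) != "unassigned"]
  list(membership = lab, modules = modules)
}

#' Module eigengene (first principal component)
#'
#' Member profiles are standardized across samples; the eigengene is the
#' first right singular vector (per-sample, unit norm), signed so that its
#' mean correlation with member profiles is non-negative.
#'
#' @param expr Matrix, module members x samples (>= 2 members, >= 2
#'   samples).
#' @return List with `eigengene` (named per-sample vector, unit norm) and
#'   `var_explained` (fraction in (0, 1\]).
#' @export
module_eigengene <- function(expr) {
  if (nrow(expr) < 2L || ncol(expr) < 2L)
    stop("need >= 2 members and >= 2 samples")
  s <- t(scale(t(expr)))
  if (anyNA(s)) stop("constant member profile(s) in module")
  sv <- svd(s)
  e <- sv$v[, 1L]
  if (mean(cor(e, t(s))) < 0) e <- -e
  e <- e / sqrt(sum(e^2))
  names(e) <- colnames(expr)
  list(eigengene = e, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Top intramodular edges by co-expression weight
#'
#' The `k` highest-weight edges among module members, ties broken by
#' lexicographic (id_i, id_j); hub rank is the intramodular degree within
#' this edge set.
#'
#' @param adjacency Adjacency matrix from [coexpr_adjacency()].
#' @param members Character vector of module member ids (>= 2 for a
#'   non-empty result).
#' @param k Number of edges to keep (default 50).
#' @return List with `edges` (data frame `from`, `to`, `weight`) and
#'   `hub_rank` (named degree vector, decreasing).
#' @export
top_edges <- function(adjacency, members, k = 50L) {
  if (k < 1L) stop("k must be >= 1")
  members <- sort(intersect(members, rownames(adjacency)))
  if (length(members) < 2L)
    return(list(edges = data.frame(from = character(0), to = character(0),
                                   weight = numeric(0)),
                hub_rank = integer(0)))
  a <- adjacency[members, members]
  idx <- which(upper.tri(a), arr.ind = TRUE)
  edges <- data.frame(from = members[idx[, 1L]], to = members[idx[, 2L]],
                      weight = a[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$from, edges$to), ]
  edges <- head(edges, k)
  rownames(edges) <- NULL
  deg <- sort(table(c(edges$from, edges$to)), decreasing = TRUE)
  list(edges = edges, hub_rank = setNames(as.integer(deg), names(deg)))
}

#' Hypergeometric term over-representation
#'
#' For each term with `K` annotated features in the population of size `N`
#' and `k` hits among the `n` module members, the upper-tail probability
#' `P(X >= k)` is computed; terms with `p < alpha` are flagged. No
#' multiplicity correction is applied by default; set `adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param module_members Character vector of module member ids (must be a
#'   subset of `population`).
#' @param term_map Data frame with columns `feature`, `term`.
#' @param population Character vector of all annotatable feature ids.
#' @param alpha Significance threshold on the (optionally adjusted) p
#'   (default 0.05).
#' @param adjust `"none"` (default, mirrors a plain p < 0.05 rule) or
#'   `"BH"`.
#' @return Data frame with `term`, `k_hits`, `n_module`, `K_annotated`,
#'   `N_population`, `p`, `significant`; terms with `K = 0` are skipped.
#' @export
hypergeom_enrich <- function(module_members, term_map, population,
                             alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!all(module_members %in% population))
    stop("module members must be a subset of the population")
  term_map <- term_map[term_map$feature %in% population, , drop = FALSE]
  N <- length(unique(population))
  n <- length(unique(module_members))
  terms <- unique(term_map$term)
  rows <- lapply(terms, function(tm) {
    annot <- unique(term_map$feature[term_map$term == tm])
    K <- length(annot)
    if (K == 0L) return(NULL)
    k <- length(intersect(module_members, annot))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k_hits = k, n_module = n, K_annotated = K,
               N_population = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), k_hits = integer(0),
                      n_module = integer(0), K_annotated = integer(0),
                      N_population = integer(0), p = numeric(0),
                      significant = logical(0)))
  p_use <- if (adjust == "BH") p.adjust(out$p, "BH") else out$p
  out$significant <- p_use < alpha
  out[order(out$p), ]
}
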