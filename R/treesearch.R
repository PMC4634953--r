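## Maximum-likelihood tree estimation: per-branch Brent optimization with
## cached partial-likelihood messages, coordinate-wise model-parameter
## fitting, NNI topology search, NJ starting trees, nonparametric
## bootstrap and outgroup rooting.

#' Neighbor-joining starting tree from p-distances
#'
#' Pairwise-deletion p-distances (sites where either taxon is missing are
#' ignored for that pair) fed to \code{ape::nj}. Pairs with no overlapping
#' determined sites get 1.5x the largest observed distance. Negative NJ
#' branch lengths are clamped to 1e-8.
#'
#' @param alignment Character matrix (rows = taxa) or compressed patterns.
#' @return An unrooted \code{phylo} tree.
#' @export
nj_start_tree <- function(alignment) {
  pat <- if (is.matrix(alignment)) compress_patterns(alignment)
         else alignment
  d <- p_distance_matrix(pat$codes, pat$weights, pat$taxa)
  if (nrow(d) < 3L) stop("need at least 3 taxa for an NJ tree")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  ape::unroot(tr)
}

## weighted pairwise-deletion p-distance over site patterns
p_distance_matrix <- function(codes, weights, taxa) {
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    vi <- codes[i, ]; vj <- codes[j, ]
    valid <- !is.na(vi) & !is.na(vj)
    denom <- sum(weights[valid])
    d[i, j] <- d[j, i] <-
      if (denom > 0) sum(weights[valid & (vi != vj)]) / denom else NA_real_
  }
  if (anyNA(d)) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- 1.5 * mx + 0.05
    diag(d) <- 0
  }
  d
}

#' Optimize branch lengths by per-branch Brent search
#'
#' Sweeps the tree in depth-first order, optimizing each branch length by
#' bounded one-dimensional search while reusing partial-likelihood
#' messages for the rest of the tree (so each candidate length costs one
#' small matrix product per rate category, not a full pruning pass).
#' Sweeps repeat until the log-likelihood gain drops below \code{ll_tol};
#' the log-likelihood never decreases because a proposed length is only
#' accepted when it does not lower the objective.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param alignment Character matrix or compressed patterns.
#' @param model A \code{subst_model}.
#' @param max_sweeps Maximum number of full-tree sweeps.
#' @param ll_tol Stop when a sweep improves the log-likelihood by less.
#' @param bounds Branch-length search interval (default [1e-8, 20]).
#' @param opt_tol Brent tolerance on the branch length.
#' @return The tree with updated lengths; attribute \code{loglik}.
#' @export
optimize_branch_lengths <- function(tree, alignment, model,
                                    max_sweeps = 5L, ll_tol = 1e-4,
                                    bounds = c(1e-8, 20), opt_tol = 1e-6) {
  pat <- if (is.matrix(alignment)) compress_patterns(alignment, model$freq)
         else alignment
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  el <- tree$edge.length
  ntip <- length(tree$tip.label)
  nedge <- nrow(edge)
  k <- model$k
  rates <- effective_rates(model)
  tipidx <- match(tree$tip.label, pat$taxa)
  if (anyNA(tipidx)) stop("tree tips missing from alignment")
  tips <- lapply(seq_len(ntip), function(i) tip_partial(pat$codes[tipidx[i], ]))
  children_edges <- split(seq_len(nedge), factor(edge[, 1],
                                                 levels = seq_len(ntip + tree$Nnode)))
  root <- ntip + 1L

  up <- replicate(k, vector("list", nedge), simplify = FALSE)
  down <- replicate(k, vector("list", nedge), simplify = FALSE)

  apply_edge <- function(msg, e, cc) {
    P <- transition_matrix(model, el[e], rates[cc])
    list(m = P %*% msg$m, lg = msg$lg)
  }
  up_msg_of <- function(e, cc) {
    v <- edge[e, 2L]
    if (v <= ntip) list(m = tips[[v]], lg = 0) else up[[cc]][[e]]
  }
  ## recompute the upward message of edge e from its child node's edges
  refresh_up <- function(e) {
    v <- edge[e, 2L]
    if (v <= ntip) return(invisible())
    for (cc in seq_len(k)) {
      acc <- NULL
      for (e2 in children_edges[[v]]) {
        part <- apply_edge(up_msg_of(e2, cc), e2, cc)
        acc <- if (is.null(acc)) part
               else list(m = acc$m * part$m, lg = acc$lg + part$lg)
      }
      up[[cc]][[e]] <<- rescale_msg(acc)
    }
  }
  edge_loglik <- function(t, e) {
    logLc <- matrix(NA_real_, ncol(pat$codes), k)
    for (cc in seq_len(k)) {
      P <- transition_matrix(model, t, rates[cc])
      um <- up_msg_of(e, cc)
      dm <- down[[cc]][[e]]
      sL <- colSums(model$freq * dm$m * (P %*% um$m))
      logLc[, cc] <- log(sL) + um$lg + dm$lg
    }
    sum(pat$weights * combine_site_loglik(logLc, pat, model))
  }

  last_ll <- -Inf
  sweep_node <- function(u, parent_edge) {
    for (e in children_edges[[u]]) {
      ## downward message: everything at u except the subtree through e
      for (cc in seq_len(k)) {
        acc <- NULL
        others <- setdiff(children_edges[[u]], e)
        for (e2 in others) {
          part <- apply_edge(up_msg_of(e2, cc), e2, cc)
          acc <- if (is.null(acc)) part
                 else list(m = acc$m * part$m, lg = acc$lg + part$lg)
        }
        if (!is.null(parent_edge) && parent_edge > 0L) {
          part <- apply_edge(down[[cc]][[parent_edge]], parent_edge, cc)
          acc <- if (is.null(acc)) part
                 else list(m = acc$m * part$m, lg = acc$lg + part$lg)
        }
        if (is.null(acc))
          acc <- list(m = matrix(1, 20, ncol(pat$codes)), lg = 0)
        down[[cc]][[e]] <<- rescale_msg(acc)
      }
      cur <- edge_loglik(el[e], e)
      opt <- stats::optimize(edge_loglik, interval = bounds, e = e,
                             maximum = TRUE, tol = opt_tol)
      if (opt$objective > cur) {
        el[e] <<- opt$maximum
        last_ll <<- opt$objective
      } else {
        last_ll <<- cur
      }
      v <- edge[e, 2L]
      if (v > ntip) {
        sweep_node(v, e)
        refresh_up(e)
      }
    }
  }

  ## initial upward pass (postorder edge order guarantees children first)
  for (e in seq_len(nedge)) refresh_up(e)
  prev <- -Inf
  for (s in seq_len(max_sweeps)) {
    sweep_node(root, NULL)
    if (last_ll - prev < ll_tol) break
    prev <- last_ll
  }
  tree$edge.length <- el
  attr(tree, "loglik") <- last_ll
  tree
}

#' Fit the rate-heterogeneity parameters by coordinate search
#'
#' Bounded one-dimensional optimization of the gamma shape (alpha in
#' [0.05, 20]) and the invariant proportion (p_inv in [0, 0.8]), repeated
#' coordinate-wise. A proposal is only accepted if it does not decrease
#' the log-likelihood.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param alignment Character matrix or compressed patterns.
#' @param model Starting \code{subst_model}.
#' @param optim_alpha,optim_pinv Logical switches per parameter.
#' @param alpha_bounds,pinv_bounds Search intervals.
#' @param rounds Number of coordinate rounds.
#' @return List with the updated \code{model} and \code{loglik}.
#' @export
optimize_model_params <- function(tree, alignment, model,
                                  optim_alpha = TRUE, optim_pinv = TRUE,
                                  alpha_bounds = c(0.05, 20),
                                  pinv_bounds = c(0, 0.8), rounds = 3L) {
  pat <- if (is.matrix(alignment)) compress_patterns(alignment, model$freq)
         else alignment
  ll <- as.numeric(log_likelihood(tree, pat, model))
  for (r in seq_len(rounds)) {
    start_ll <- ll
    if (optim_alpha) {
      opt <- stats::optimize(function(a)
        as.numeric(log_likelihood(tree, pat, set_model_params(model, alpha = a))),
        interval = alpha_bounds, maximum = TRUE, tol = 1e-4)
      if (opt$objective > ll) {
        model <- set_model_params(model, alpha = opt$maximum)
        ll <- opt$objective
      }
    }
    if (optim_pinv) {
      opt <- stats::optimize(function(p)
        as.numeric(log_likelihood(tree, pat, set_model_params(model, p_inv = p))),
        interval = pinv_bounds, maximum = TRUE, tol = 1e-4)
      if (opt$objective > ll) {
        model <- set_model_params(model, p_inv = opt$maximum)
        ll <- opt$objective
      }
    }
    if (ll - start_ll < 1e-3) break
  }
  list(model = model, loglik = ll)
}

## rows of tree$edge whose child is an internal node
internal_edges <- function(tree) {
  which(tree$edge[, 2] > length(tree$tip.label))
}

## one NNI rearrangement: swap child `which` of the edge's lower node with
## a fixed neighbouring subtree of the upper node
nni_swap <- function(tree, e, which = 1L) {
  edge <- tree$edge
  u <- edge[e, 1L]; v <- edge[e, 2L]
  cv <- which(edge[, 1L] == v)
  cu <- setdiff(which(edge[, 1L] == u), e)
  if (length(cv) < 2L || length(cu) < 1L)
    stop("edge is not an internal edge eligible for NNI")
  ci <- cv[which]
  wv <- cu[1L]
  edge[ci, 1L] <- u
  edge[wv, 1L] <- v
  tree$edge <- edge
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "postorder")
}

#' All nearest-neighbour-interchange neighbours of a tree
#'
#' @param tree Unrooted binary \code{phylo} tree.
#' @return List of trees (two per internal edge), branch lengths carried
#'   over from the input.
#' @export
nni_neighbors <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ie <- internal_edges(tree)
  out <- list()
  for (e in ie) for (w in 1:2)
    out[[length(out) + 1L]] <- nni_swap(tree, e, w)
  out
}

#' NNI hill-climbing search for the maximum-likelihood topology
#'
#' Starting from \code{start_tree} (default: NJ on p-distances) with
#' optimized branch lengths, evaluates both NNI rearrangements of every
#' internal edge, accepts the best strictly improving one, re-optimizes
#' branch lengths and repeats until no rearrangement improves the
#' log-likelihood. Deterministic given its inputs. Trees with fewer than
#' four taxa are returned unchanged.
#'
#' @param start_tree \code{phylo} starting tree (NULL for NJ start).
#' @param alignment Character matrix or compressed patterns.
#' @param model A \code{subst_model}.
#' @param max_iter Cap on accepted rearrangements.
#' @param branch_sweeps Sweeps used when re-optimizing after an accept.
#' @return The locally optimal tree; attribute \code{loglik}.
#' @export
nni_search <- function(start_tree, alignment, model, max_iter = 25L,
                       branch_sweeps = 3L) {
  pat <- if (is.matrix(alignment)) compress_patterns(alignment, model$freq)
         else alignment
  if (is.null(start_tree)) start_tree <- nj_start_tree(pat)
  if (length(start_tree$tip.label) < 4L) {
    attr(start_tree, "loglik") <-
      as.numeric(log_likelihood(start_tree, pat, model))
    return(start_tree)
  }
  cur <- optimize_branch_lengths(start_tree, pat, model,
                                 max_sweeps = branch_sweeps)
  ll <- attr(cur, "loglik")
  for (it in seq_len(max_iter)) {
    nbs <- nni_neighbors(cur)
    scores <- vapply(nbs, function(tr)
      as.numeric(log_likelihood(tr, pat, model)), numeric(1))
    best <- which.max(scores)
    cand <- optimize_branch_lengths(nbs[[best]], pat, model,
                                    max_sweeps = branch_sweeps)
    if (attr(cand, "loglik") > ll + 1e-6) {
      cur <- cand
      ll <- attr(cand, "loglik")
    } else {
      break
    }
  }
  attr(cur, "loglik") <- ll
  cur
}

#' Full maximum-likelihood fit
#'
#' Convenience driver: NJ starting tree, alternating branch-length and
#' model-parameter optimization, then NNI topology search.
#'
#' @param alignment Character matrix (rows = taxa).
#' @param model Starting \code{subst_model} (default JTT, alpha free).
#' @param optimize_model Fit alpha and p_inv (default TRUE).
#' @param start_tree Optional starting topology.
#' @return List: \code{tree}, \code{model}, \code{loglik}.
#' @export
ml_tree_search <- function(alignment, model = jtt_model(p_inv = 0.1, alpha = 1),
                           optimize_model = TRUE, start_tree = NULL) {
  pat <- compress_patterns(alignment, model$freq)
  if (is.null(start_tree)) start_tree <- nj_start_tree(pat)
  tree <- optimize_branch_lengths(start_tree, pat, model)
  if (optimize_model) {
    fit <- optimize_model_params(tree, pat, model)
    model <- fit$model
    tree <- optimize_branch_lengths(tree, pat, model)
  }
  tree <- nni_search(tree, pat, model)
  if (optimize_model) {
    fit <- optimize_model_params(tree, pat, model)
    model <- fit$model
    tree <- optimize_branch_lengths(tree, pat, model)
  }
  list(tree = tree, model = model, loglik = attr(tree, "loglik"))
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement, re-runs the tree search
#' per replicate (NJ start, branch-length optimization and NNI under the
#' fixed fitted model), and maps bipartition frequencies (percent) onto
#' the full-data ML tree's internal nodes.
#'
#' @param alignment Character matrix (rows = taxa).
#' @param model Fitted \code{subst_model} (held fixed across replicates).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed controlling all resampling.
#' @param ml_tree Full-data ML tree; fitted internally when NULL.
#' @param search Run the NNI search per replicate (TRUE) or keep the NJ
#'   replicate topologies (FALSE, faster and cruder).
#' @return The ML tree with percentage supports in \code{node.label};
#'   replicate trees in attribute \code{boot_trees}.
#' @export
bootstrap_support <- function(alignment, model, n_reps = 100L, seed = 1L,
                              ml_tree = NULL, search = TRUE) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  pat <- compress_patterns(alignment, model$freq)
  if (is.null(ml_tree)) {
    fit <- ml_tree_search(alignment, model)
    ml_tree <- fit$tree
    model <- fit$model
  }
  nsites <- length(pat$site_pattern)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  boot_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    w <- tabulate(pat$site_pattern[sample.int(nsites, replace = TRUE)],
                  nbins = ncol(pat$codes))
    keep <- w > 0L
    patb <- list(codes = pat$codes[, keep, drop = FALSE],
                 weights = as.numeric(w[keep]),
                 const_pi = pat$const_pi[keep],
                 site_pattern = NULL, taxa = pat$taxa)
    t0 <- nj_start_tree(patb)
    boot_trees[[r]] <-
      if (search) nni_search(t0, patb, model, branch_sweeps = 2L)
      else t0
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(ml_tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ml_tree$node.label <- round(100 * counts / n_reps, 1)
  attr(ml_tree, "boot_trees") <- boot_trees
  ml_tree
}

#' Root a tree on its outgroup's pendant edge
#'
#' Places the root at the midpoint of the outgroup's pendant edge. Under a
#' reversible model the root placement does not change the likelihood
#' (pulley principle); rooting is display/interpretation only.
#'
#' @param tree \code{phylo} tree containing \code{outgroup_label}.
#' @param outgroup_label Tip label of the outgroup taxon.
#' @return Rooted \code{phylo} with the outgroup as a child of the root.
#' @export
root_at_outgroup <- function(tree, outgroup_label) {
  if (!outgroup_label %in% tree$tip.label)
    stop("outgroup '", outgroup_label, "' not among tip labels")
  tr <- ape::root(ape::unroot(tree), outgroup = outgroup_label,
                  resolve.root = TRUE, edgelabel = TRUE)
  root <- length(tr$tip.label) + 1L
  ce <- which(tr$edge[, 1] == root)
  if (length(ce) == 2L) {            # split the pendant edge at its midpoint
    tot <- sum(tr$edge.length[ce])
    tr$edge.length[ce] <- tot / 2
  }
  tr
}

#' Robinson-Foulds distance between two topologies
#'
#' @param tree_a,tree_b \code{phylo} trees over the same taxa.
#' @return The PH85 bipartition distance (0 when the unrooted topologies
#'   agree).
#' @export
rf_distance <- function(tree_a, tree_b) {
  as.numeric(ape::dist.topo(ape::unroot(tree_a), ape::unroot(tree_b)))
}
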