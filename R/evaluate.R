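#' Precision, recall and F1 of an inferred ancestral network
#'
#' Edge-set comparison at the homology-group level. With no predicted edges
#' precision is reported as 1 (with a warning attribute), so F1 collapses to
#' 0 through recall unless the truth is also empty.
#'
#' @param inferred,truth [interaction_graph()]s over comparable node ids.
#' @return named numeric vector \code{c(precision, recall, f1)}.
#' @export
precision_recall_f1 <- function(inferred, truth) {
  if (inferred$directed != truth$directed)
    stop("inferred and truth disagree on directedness")
  if (!length(intersect(inferred$nodes, truth$nodes)) &&
      length(inferred$nodes) && length(truth$nodes))
    stop("inferred and truth share no node ids")
  key <- function(g) if (nrow(g$edges))
    paste(g$edges[, 1], g$edges[, 2], sep = "\r") else character(0)
  ki <- key(inferred); kt <- key(truth)
  tp <- length(intersect(ki, kt))
  fp <- length(setdiff(ki, kt))
  fn <- length(setdiff(kt, ki))
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  out <- c(precision = p, recall = r, f1 = f1)
  if (tp + fp == 0) attr(out, "no_predictions") <- TRUE
  out
}

#' F1 excluding homology groups lost in both lineages
#'
#' Interactions incident to a group with no Present descendant in either
#' extant network are unrecoverable in principle; this score removes them
#' (from truth and prediction alike) before comparing. Recall can only rise.
#'
#' @param inferred,truth as in [precision_recall_f1()].
#' @param F1,F2 the lineage [duplication_forest()]s.
#' @return named numeric vector \code{c(precision, recall, f1)}.
#' @export
f1_excluding_lost <- function(inferred, truth, F1, F2) {
  surviving <- function(F) unique(F$group[F$present %in% TRUE])
  alive <- union(surviving(F1), surviving(F2))
  lost <- setdiff(union(F1$group[F1$roots], F2$group[F2$roots]), alive)
  strip <- function(g) {
    if (!nrow(g$edges)) return(g)
    keep <- !(g$edges[, 1] %in% lost | g$edges[, 2] %in% lost)
    interaction_graph(setdiff(g$nodes, lost), g$edges[keep, , drop = FALSE],
                      directed = g$directed, selfloops = g$selfloops)
  }
  precision_recall_f1(strip(inferred), strip(truth))
}

#' Reconstruct and score one simulated instance
#'
#' @param instance a \code{sim_instance} from [generate_instance()].
#' @param c_add,c_loss,alpha cost model for the reconstruction.
#' @return list with the inferred ancestor and both scores.
#' @export
score_instance <- function(instance, c_add = 1, c_loss = 1, alpha = 0) {
  inf <- infer_ancestor(instance$F1, instance$F2, instance$G1, instance$G2,
                        c_add = c_add, c_loss = c_loss, alpha = alpha)
  list(ancestor = inf,
       score = precision_recall_f1(inf, instance$X),
       score_excluding_lost = f1_excluding_lost(inf, instance$X,
                                                instance$F1, instance$F2))
}

#' Divergence sweep: reconstruction quality vs evolutionary distance
#'
#' For each number of post-speciation operations, generates accepted
#' instances, reconstructs the common ancestor and reports quartiles of the
#' F1 score (plain and excluding groups lost in both lineages).
#'
#' @param params base [sim_params()] (its \code{ops_per_lineage} is swept).
#' @param distances integer vector of per-lineage operation counts.
#' @param replicates instances per distance.
#' @param seed RNG seed.
#' @return data frame, one row per distance.
#' @export
run_divergence_sweep <- function(params, distances, replicates = 100L,
                                 seed = 1L) {
  set.seed(seed)
  rows <- lapply(distances, function(d) {
    p <- params; p$ops_per_lineage <- as.integer(d)
    f1 <- f1x <- numeric(replicates)
    nX <- integer(replicates)
    for (i in seq_len(replicates)) {
      inst <- generate_instance(p)
      sc <- score_instance(inst)
      f1[i] <- sc$score[["f1"]]; f1x[i] <- sc$score_excluding_lost[["f1"]]
      nX[i] <- length(inst$X$nodes)
    }
    q <- stats::quantile(f1, c(.25, .5, .75))
    qx <- stats::quantile(f1x, c(.25, .5, .75))
    data.frame(distance = d, n_ancestor_mean = mean(nX),
               f1_q1 = q[1], f1_median = q[2], f1_q3 = q[3],
               f1x_q1 = qx[1], f1x_median = qx[2], f1x_q3 = qx[3],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Parameter sweep: reconstruction quality across model settings
#'
#' Each grid row overrides fields of \code{params} (e.g. \code{p_ndup},
#' \code{p_innovation}). Per grid point the sweep simulates, filters,
#' reconstructs the ancestor, and also fits each lineage's history with
#' [reconstruct_history()] to record loop-breaking statistics (iterations
#' and relative excess of the valid cost over the DP lower bound).
#'
#' @param params base [sim_params()].
#' @param grid data frame of parameter overrides.
#' @param replicates instances per grid point.
#' @param seed RNG seed.
#' @return data frame, one row per grid point.
#' @export
run_parameter_sweep <- function(params, grid, replicates = 20L, seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(grid)), function(gi) {
    p <- params
    for (nm in names(grid)) p[[nm]] <- grid[[nm]][gi]
    if (p$model %in% c("DDM", "DIM")) {
      pr <- c(p$p["ndup"], p$p["nloss"], p$p["egain"], p$p["eloss"])
      for (nm in intersect(names(grid), c("p_ndup", "p_nloss", "p_egain", "p_eloss")))
        pr[[sub("^p_", "", nm)]] <- grid[[nm]][gi]
      p$p <- pr / sum(pr)
    }
    f1 <- numeric(replicates); excess <- numeric(0); broken <- 0L
    for (i in seq_len(replicates)) {
      inst <- generate_instance(p)
      f1[i] <- score_instance(inst)$score[["f1"]]
      for (ln in 1:2) {
        F <- if (ln == 1) inst$F1 else inst$F2
        G <- if (ln == 1) inst$G1 else inst$G2
        fit <- reconstruct_history(F, G, seed = i)
        if (fit$iterations > 0) broken <- broken + 1L
        excess <- c(excess, if (fit$lower_bound > 0)
          (fit$cost - fit$lower_bound) / fit$lower_bound else 0)
      }
    }
    q <- stats::quantile(f1, c(.25, .5, .75))
    cbind(grid[gi, , drop = FALSE],
          data.frame(f1_q1 = q[1], f1_median = q[2], f1_q3 = q[3],
                     histories_needing_breaking = broken,
                     max_relative_excess = max(excess), row.names = NULL))
  })
  do.call(rbind, rows)
}
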