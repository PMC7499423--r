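#' Size-weighted constant Potts model objective
#'
#' Quality of a partition under the constant Potts model (CPM) with node
#' sizes: `sum over communities c of [W_c - gamma * N_c * (N_c - 1) / 2]`,
#' where `W_c` is the total weight of intra-community edges and `N_c` the
#' sum of node sizes in c.  The resolution `gamma` is an absolute density
#' threshold: a group of nodes is worth keeping together only if its
#' internal edge density (per size-pair) exceeds `gamma`.
#'
#' @param g a `similarity_graph`.
#' @param membership integer community id per node.
#' @param gamma resolution parameter (> 0).
#' @return The objective value (a single number).
#' @export
cpm_objective <- function(g, membership, gamma) {
  stopifnot(length(membership) == nrow(g$nodes))
  w_in <- if (nrow(g$edges) > 0) {
    sum(g$edges$weight[membership[g$edges$from] == membership[g$edges$to]])
  } else 0
  sizes <- g$nodes$size
  comm_sizes <- tapply(sizes, membership, sum)
  w_in - gamma * sum(comm_sizes * (comm_sizes - 1)) / 2
}

#' Cluster new cells with frozen atlas annotations
#'
#' The atlas-aware variant of Leiden community detection.  Initialization
#' places all atlas nodes of a type in one seed community per type and
#' every new cell in its own singleton.  Sweeps of local moves are then
#' restricted to *new* nodes only: each new node moves to the neighboring
#' community (or a fresh singleton) that maximizes the CPM objective gain;
#' atlas nodes never move.  When node-level sweeps converge, communities
#' are aggregated into super-nodes and the sweeps repeat at the aggregated
#' level, so whole groups of new cells can join an atlas community; any
#' super-node containing atlas nodes is frozen.  Because frozen communities
#' never move and moves never combine two frozen communities, no reachable
#' state splits an atlas type or merges two atlas labels — the atlas types
#' are fully determined by the atlas.  Terminates when neither level makes
#' a move or after `max_sweeps` sweeps in total; at termination no single
#' new-node move can strictly increase the objective.
#'
#' @param g a `similarity_graph` with labeled atlas nodes.
#' @param resolution CPM resolution gamma (> 0); keep it small (the useful
#'   regime is below 0.01) to avoid splitting communities into subclusters.
#' @param seed integer seed for the per-sweep random move order.
#' @param max_sweeps maximum number of full sweeps (default 100).
#' @return A `membership` object: list with `community` (integer per node),
#'   `community_label` (named chr; atlas label per labeled community id,
#'   `NA` for novel), `objective` (final CPM value), `trace` (objective
#'   after each sweep), `n_sweeps`.
#' @export
cluster_with_annotations <- function(g, resolution = 0.001, seed = 0,
                                     max_sweeps = 100) {
  stopifnot(inherits(g, "similarity_graph"))
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  n <- nrow(g$nodes)
  if (n == 0) stop("graph has no nodes", call. = FALSE)
  is_atlas <- g$nodes$is_atlas
  sizes <- g$nodes$size
  labels <- g$nodes$label
  atlas_types <- unique(labels[is_atlas])
  n_types <- length(atlas_types)

  # seed communities: 1..n_types for atlas labels, then singletons
  comm <- integer(n)
  comm[is_atlas] <- match(labels[is_atlas], atlas_types)
  new_nodes <- which(!is_atlas)
  comm[new_nodes] <- n_types + seq_along(new_nodes)

  gamma <- resolution
  trace <- numeric(0)
  n_sweeps <- 0L

  # One pass of greedy local moves on an arbitrary (possibly aggregated)
  # graph: movable nodes relocate to the neighboring community (or a fresh
  # singleton) with the best CPM gain.  Returns the updated membership and
  # whether anything moved.
  sweep_once <- function(edges, sz, movable, cm) {
    adj <- replicate(length(sz), list(nb = integer(0), w = numeric(0)),
                     simplify = FALSE)
    if (nrow(edges) > 0) {
      ends <- c(edges$from, edges$to)
      other <- c(edges$to, edges$from)
      wts <- rep(edges$weight, 2)
      for (i in unique(ends)) {
        sel <- ends == i
        adj[[i]] <- list(nb = other[sel], w = wts[sel])
      }
    }
    csize <- numeric(max(cm) + length(movable) + 1L)
    for (c in unique(cm)) csize[c] <- sum(sz[cm == c])
    next_id <- max(cm) + 1L
    moved <- FALSE
    for (i in movable[sample.int(length(movable))]) {
      a <- cm[i]
      s_i <- sz[i]
      nb <- adj[[i]]$nb
      if (length(nb) > 0) {
        w_to <- tapply(adj[[i]]$w, cm[nb], sum)
        cand <- as.integer(names(w_to))
        w_to <- as.numeric(w_to)
      } else {
        cand <- integer(0); w_to <- numeric(0)
      }
      stay_gain <- (if (a %in% cand) w_to[match(a, cand)] else 0) -
        gamma * s_i * (csize[a] - s_i)
      others <- cand[cand != a]
      # gain of joining c: w_i->c - gamma * s_i * S_c; fresh singleton: 0
      gains <- c(if (length(others) > 0)
                   w_to[match(others, cand)] - gamma * s_i * csize[others]
                 else numeric(0),
                 0)
      cand_all <- c(others, 0L)
      best <- which.max(gains)        # first max: deterministic tie-break
      if (gains[best] > stay_gain + 1e-12) {
        target <- cand_all[best]
        if (target == 0L) {
          target <- next_id
          next_id <- next_id + 1L
          if (target > length(csize)) csize <- c(csize, numeric(target))
        }
        csize[a] <- csize[a] - s_i
        csize[target] <- csize[target] + s_i
        cm[i] <- target
        moved <- TRUE
      }
    }
    list(cm = cm, moved = moved)
  }

  record <- function(cm) trace <<- c(trace, cpm_objective(g, cm, gamma))

  edges0 <- g$edges
  if (length(new_nodes) > 0 && n_sweeps < max_sweeps) {
    withr::with_seed(seed, {
      repeat {
        # node-level sweeps until converged
        moved_any <- FALSE
        while (n_sweeps < max_sweeps) {
          n_sweeps <- n_sweeps + 1L
          r <- sweep_once(edges0, sizes, new_nodes, comm)
          comm <- r$cm
          record(comm)
          if (!r$moved) break
          moved_any <- TRUE
        }
        # aggregation: whole communities of new cells become movable
        # super-nodes; communities holding atlas nodes are frozen, which
        # enforces no-split and no-merge of atlas types at every level
        while (n_sweeps < max_sweeps) {
          ids <- sort(unique(comm))
          meta_of <- match(comm, ids)
          k <- length(ids)
          if (k <= 1) break
          mfrom <- meta_of[edges0$from]
          mto <- meta_of[edges0$to]
          keep <- mfrom != mto
          lo <- pmin(mfrom[keep], mto[keep])
          hi <- pmax(mfrom[keep], mto[keep])
          key <- (lo - 1) * k + hi
          wsum <- rowsum(edges0$weight[keep], key)
          ukey <- as.numeric(rownames(wsum))
          meta_edges <- tibble::tibble(
            from = as.integer((ukey - 1) %/% k + 1),
            to = as.integer((ukey - 1) %% k + 1),
            weight = as.numeric(wsum))
          meta_sizes <- as.numeric(rowsum(sizes, meta_of))
          frozen <- as.logical(rowsum(as.numeric(is_atlas), meta_of) > 0)
          movable_meta <- which(!frozen)
          if (length(movable_meta) == 0) break
          n_sweeps <- n_sweeps + 1L
          r <- sweep_once(meta_edges, meta_sizes, movable_meta, seq_len(k))
          if (!r$moved) break
          comm <- r$cm[meta_of]
          record(comm)
          moved_any <- TRUE
        }
        if (!moved_any || n_sweeps >= max_sweeps) break
      }
    })
  }

  # compact ids: atlas communities become 1..n_types, novel renumbered after
  atlas_comm_of_type <- comm[match(atlas_types, labels)]
  in_atlas_comm <- comm %in% atlas_comm_of_type
  out <- integer(n)
  out[in_atlas_comm] <- match(comm[in_atlas_comm], atlas_comm_of_type)
  novel_ids <- unique(comm[!in_atlas_comm])
  out[!in_atlas_comm] <- n_types + match(comm[!in_atlas_comm], novel_ids)
  community_label <- c(atlas_types, rep(NA_character_, length(novel_ids)))
  names(community_label) <- as.character(seq_along(community_label))

  m <- structure(list(community = out,
                      community_label = community_label,
                      objective = cpm_objective(g, out, gamma),
                      trace = trace,
                      n_sweeps = n_sweeps),
                 class = "membership")
  validate_membership(g, m)
  m
}

validate_membership <- function(g, m) {
  comm <- m$community
  is_atlas <- g$nodes$is_atlas
  labels <- g$nodes$label
  # no atlas type split, no two labels in one community
  for (t in unique(labels[is_atlas])) {
    cs <- unique(comm[is_atlas & labels == t])
    if (length(cs) != 1) stop("atlas type split across communities: ", t, call. = FALSE)
  }
  bylab <- tapply(labels[is_atlas], comm[is_atlas],
                  function(x) length(unique(x)))
  if (any(bylab > 1)) stop("two atlas labels share a community", call. = FALSE)
  invisible(m)
}

#' @export
print.membership <- function(x, ...) {
  n_novel <- sum(is.na(x$community_label[unique(as.character(x$community))]))
  cat(sprintf("<membership> %d nodes, %d communities (%d novel), CPM objective %.4g\n",
              length(x$community), length(unique(x$community)), n_novel,
              x$objective))
  invisible(x)
}

#' Audit single-move optimality of a partition
#'
#' Exhaustively tries every move of every new node to every existing
#' community (and to a fresh singleton) and returns the largest objective
#' improvement found.  A converged clustering returns a value <= 0 (up to
#' numerical noise).
#'
#' @param g a `similarity_graph`.
#' @param m a `membership`.
#' @param gamma the resolution used.
#' @return Largest achievable single-move gain (number).
#' @export
audit_node_optimality <- function(g, m, gamma) {
  comm <- m$community
  base <- cpm_objective(g, comm, gamma)
  best <- 0
  targets <- c(unique(comm), max(comm) + 1L)
  for (i in which(!g$nodes$is_atlas)) {
    for (tg in targets) {
      if (tg == comm[i]) next
      trial <- comm
      trial[i] <- tg
      best <- max(best, cpm_objective(g, trial, gamma) - base)
    }
  }
  best
}

#' Assign atlas labels or novel-cluster names to new cells
#'
#' New cells in a community that contains an atlas type inherit its label;
#' communities without an atlas node are numbered `novel_1`, `novel_2`, ...
#' in decreasing size order (ties broken by smallest member index).
#' Novel communities below `min_novel_cluster_size` are flagged
#' `"unassigned"` instead.
#'
#' @param g the clustered `similarity_graph`.
#' @param m a `membership` from [cluster_with_annotations()].
#' @param min_novel_cluster_size minimum cells for a reported novel cluster
#'   (default 0 = report everything).
#' @return A tibble over *new* cells: `cell_id`, `assigned_label`,
#'   `community_id`, `is_novel`.
#' @export
assign_labels <- function(g, m, min_novel_cluster_size = 0) {
  comm <- m$community
  lab_of_comm <- m$community_label[as.character(comm)]
  novel_comms <- unique(comm[is.na(lab_of_comm)])
  if (length(novel_comms) > 0) {
    sz <- vapply(novel_comms, function(c) sum(comm == c), numeric(1))
    first_member <- vapply(novel_comms, function(c) min(which(comm == c)), numeric(1))
    ord <- order(-sz, first_member)
    novel_comms <- novel_comms[ord]
    sz <- sz[ord]
    novel_names <- paste0("novel_", seq_along(novel_comms))
    novel_names[sz < min_novel_cluster_size] <- "unassigned"
  } else {
    novel_names <- character(0)
  }
  new_idx <- which(!g$nodes$is_atlas)
  lab <- lab_of_comm[new_idx]
  is_novel <- is.na(lab)
  if (any(is_novel)) {
    lab[is_novel] <- novel_names[match(comm[new_idx][is_novel], novel_comms)]
  }
  tibble::tibble(cell_id = g$nodes$id[new_idx],
                 assigned_label = unname(lab),
                 community_id = comm[new_idx],
                 is_novel = unname(is_novel))
}
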