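# Connected components of the bipartite active/detection candidate graph.
candidate_components <- function(pairs, n_active, n_det) {
  parent <- seq_len(n_active + n_det)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(pairs$active)) {
    a <- find(pairs$active[k])
    b <- find(n_active + pairs$det[k])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n_active + n_det), find, integer(1))
}

# Exact minimum-cost assignment within one subnetwork by depth-first
# enumeration with pruning. Cost: squared displacement per link, plus
# search_range^2 for every active particle left unlinked.
best_assignment <- function(cost_list, sr2) {
  n <- length(cost_list)
  best <- list(cost = Inf, assign = rep(NA_integer_, n))
  assign <- rep(NA_integer_, n)
  used <- integer(0)
  rec <- function(i, acc) {
    if (acc >= best$cost) return(invisible(NULL))
    if (i > n) {
      best <<- list(cost = acc, assign = assign)
      return(invisible(NULL))
    }
    cands <- cost_list[[i]]
    if (length(cands$det) > 0) {
      ord <- order(cands$cost)
      for (k in ord) {
        j <- cands$det[k]
        if (j %in% used) next
        assign[i] <<- j
        used <<- c(used, j)
        rec(i + 1L, acc + cands$cost[k])
        used <<- used[-length(used)]
        assign[i] <<- NA_integer_
      }
    }
    rec(i + 1L, acc + sr2) # leave this particle unlinked
  }
  rec(1L, 0)
  best$assign
}

greedy_assignment <- function(cost_list, sr2) {
  n <- length(cost_list)
  edges <- list(
    active = rep(seq_len(n), vapply(cost_list, function(d) length(d$det), 1L)),
    det = unlist(lapply(cost_list, `[[`, "det")),
    cost = unlist(lapply(cost_list, `[[`, "cost"))
  )
  assign <- rep(NA_integer_, n)
  if (length(edges$det) == 0) return(assign)
  ord <- order(edges$cost, edges$active, edges$det)
  used <- logical(max(edges$det))
  for (k in ord) {
    i <- edges$active[k]; j <- edges$det[k]
    if (is.na(assign[i]) && !used[j]) {
      assign[i] <- j
      used[j] <- TRUE
    }
  }
  assign
}

#' Link detections into trajectories
#'
#' Frame-to-frame linking in the Crocker-Grier spirit: between consecutive
#' frames, particles are matched to detections within `search_range` pixels
#' so that the total squared displacement is minimal (exact enumeration
#' within connected candidate subnetworks up to `optimal_cap` particles,
#' deterministic greedy matching above it). A particle missing for up to
#' `memory` frames may resume its identity at its last known position;
#' otherwise unmatched detections start new particles. Single-point tracks
#' are dropped.
#'
#' @param detections Tibble `(frame, x, y, ...)` from [locate_stack()];
#'   coordinates in pixels, frames 0-based integers.
#' @param search_range Maximum per-frame displacement, pixels.
#' @param memory Frames a particle may go undetected without losing its id.
#' @param optimal_cap Largest subnetwork solved exactly.
#' @param hard_cap Subnetworks larger than this raise an error advising a
#'   smaller `search_range`.
#' @return Tibble with the input columns plus `particle`, ordered by particle
#'   then frame.
#' @export
link_features <- function(detections, search_range, memory = 0L,
                          optimal_cap = 7L, hard_cap = 60L) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y") %in% names(detections)))
  check_positive(search_range, "search_range")
  memory <- check_count(memory, "memory", min = 0L)
  empty <- detections[0, , drop = FALSE]
  empty$particle <- integer()
  if (nrow(detections) == 0L) return(as_tibble(empty))

  detections <- detections |> arrange(.data$frame, .data$y, .data$x)
  detections$particle <- NA_integer_
  sr2 <- search_range^2
  next_id <- 1L
  # active particles as parallel vectors: id, position, missed frames
  a_id <- integer(); a_x <- double(); a_y <- double(); a_miss <- integer()
  frame_seq <- seq(min(detections$frame), max(detections$frame))
  det_rows <- split(seq_len(nrow(detections)), detections$frame)
  particle_col <- rep(NA_integer_, nrow(detections))

  for (f in frame_seq) {
    rows <- det_rows[[as.character(f)]]
    nd <- length(rows)
    na <- length(a_id)
    dx <- detections$x[rows]; dy <- detections$y[rows]
    assign <- rep(NA_integer_, na)
    if (na > 0 && nd > 0) {
      d2 <- outer(a_x, dx, `-`)^2 + outer(a_y, dy, `-`)^2
      pairs_idx <- which(d2 <= sr2, arr.ind = TRUE)
      if (nrow(pairs_idx) > 0) {
        pairs <- list(active = pairs_idx[, 1], det = pairs_idx[, 2],
                      cost = d2[pairs_idx])
        if (!anyDuplicated(pairs$active) && !anyDuplicated(pairs$det)) {
          # at most one candidate per particle and per detection: every
          # subnetwork is a single pair, so direct linking is optimal
          assign[pairs$active] <- pairs$det
        } else {
          comp <- candidate_components(pairs, na, nd)
          for (cid in unique(comp[pairs$active])) {
            in_comp_active <- which(comp[seq_len(na)] == cid)
            in_comp_det <- which(comp[na + seq_len(nd)] == cid)
            if (length(in_comp_active) + length(in_comp_det) > hard_cap) {
              abort(sprintf(
                paste0("Linking subnetwork of %d particles and %d detections ",
                       "exceeds hard_cap = %d; reduce `search_range`."),
                length(in_comp_active), length(in_comp_det), hard_cap),
                class = "ptmr_link_subnetwork")
            }
            cost_list <- lapply(in_comp_active, function(i) {
              sel <- pairs$active == i
              list(det = pairs$det[sel], cost = pairs$cost[sel])
            })
            sol <- if (length(in_comp_active) <= optimal_cap) {
              best_assignment(cost_list, sr2)
            } else {
              greedy_assignment(cost_list, sr2)
            }
            assign[in_comp_active] <- sol
          }
        }
      }
    }
    if (nd > 0) {
      li <- which(!is.na(assign))
      linked_dets <- assign[li]
      particle_col[rows[linked_dets]] <- a_id[li]
      if (length(li) > 0) {
        a_x[li] <- dx[linked_dets]
        a_y[li] <- dy[linked_dets]
        a_miss[li] <- 0L
      }
      # new particles from unmatched detections
      new_dets <- setdiff(seq_len(nd), linked_dets)
      if (length(new_dets) > 0) {
        ids <- next_id + seq_along(new_dets) - 1L
        next_id <- next_id + length(new_dets)
        particle_col[rows[new_dets]] <- ids
        a_id <- c(a_id, ids)
        a_x <- c(a_x, dx[new_dets])
        a_y <- c(a_y, dy[new_dets])
        a_miss <- c(a_miss, rep(0L, length(new_dets)))
      }
    }
    # age unmatched actives, retire beyond memory
    miss_idx <- if (nd > 0) which(is.na(assign)) else seq_len(na)
    if (length(miss_idx) > 0) {
      a_miss[miss_idx] <- a_miss[miss_idx] + 1L
      keep <- a_miss <= memory
      if (!all(keep)) {
        a_id <- a_id[keep]; a_x <- a_x[keep]; a_y <- a_y[keep]
        a_miss <- a_miss[keep]
      }
    }
  }
  detections$particle <- particle_col
  out <- detections |>
    group_by(.data$particle) |>
    filter(n() >= 2L) |>
    ungroup() |>
    arrange(.data$particle, .data$frame)
  ptmr_log("link_features: %d detections -> %d trajectories (%d singletons dropped).",
           nrow(detections), length(unique(out$particle)),
           length(unique(detections$particle)) - length(unique(out$particle)))
  as_tibble(out |> select("particle", everything()))
}

#' Filter trajectories by recorded duration
#'
#' Keeps trajectories whose recorded duration,
#' `(last_frame - first_frame) / frame_rate`, is at least `min_duration`
#' seconds. With the sperm defaults (20 fps, 1 s) a track must span at least
#' 21 frames.
#'
#' @param tracks Tibble `(particle, frame, ...)`.
#' @param min_duration Minimum duration, seconds.
#' @param frame_rate Acquisition rate, Hz.
#' @return The filtered tibble, input order preserved.
#' @export
filter_trajectories <- function(tracks, min_duration, frame_rate) {
  check_tracks(tracks)
  check_nonneg(min_duration, "min_duration")
  check_positive(frame_rate, "frame_rate")
  if (nrow(tracks) == 0L) return(tracks)
  out <- tracks |>
    group_by(.data$particle) |>
    filter((max(.data$frame) - min(.data$frame)) / frame_rate >= min_duration) |>
    ungroup()
  if (nrow(out) == 0L) {
    warn("All trajectories were removed by the duration filter.")
  }
  ptmr_log("filter_trajectories: kept %d of %d tracks (min_duration = %gs).",
           length(unique(out$particle)), length(unique(tracks$particle)),
           min_duration)
  out
}
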