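# Vascular network architecture metrics: junction count and tubule length
# per field of view, from binarized network images.
#
# Definitions: a junction is a skeleton point with at least 3 neighbors
# (adjacent junction pixels are merged into one junction node); a tubule is
# a skeleton element bounded by two junctions or by a junction and an
# endpoint. Lengths are geodesic along the skeleton: 1 px per axial step,
# sqrt(2) px per diagonal step, converted to micrometers.

# Zhang-Suen thinning to a 1-px-wide skeleton, vectorized over the image.
zhang_suen_skeleton <- function(m) {
  stopifnot(is.logical(m))
  img <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  img[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m * 1L
  H <- nrow(img); W <- ncol(img)
  core_r <- 2:(H - 1L); core_c <- 2:(W - 1L)
  shift <- function(x, dr, dc) {
    x[core_r + dr, core_c + dc]
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- img[core_r, core_c]
      p2 <- shift(img, -1L, 0L); p3 <- shift(img, -1L, 1L)
      p4 <- shift(img, 0L, 1L);  p5 <- shift(img, 1L, 1L)
      p6 <- shift(img, 1L, 0L);  p7 <- shift(img, 1L, -1L)
      p8 <- shift(img, 0L, -1L); p9 <- shift(img, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (pass == 1L) {
        cond <- p == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- p == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        p[cond] <- 0L
        img[core_r, core_c] <- p
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[core_r, core_c] == 1L
}

# 8-neighbor count of each skeleton pixel.
neighbor_counts <- function(sk) {
  k <- matrix(1, 3, 3); k[2, 2] <- 0
  p <- matrix(0, nrow(sk) + 2L, ncol(sk) + 2L)
  p[2:(nrow(sk) + 1L), 2:(ncol(sk) + 1L)] <- sk * 1
  cnt <- EBImage::filter2(p, k, boundary = "circular")
  round(as.matrix(cnt)[2:(nrow(sk) + 1L), 2:(ncol(sk) + 1L)]) * sk
}

# Number of distinct skeleton branches meeting at each pixel: 0->1
# transitions around the circular 8-neighborhood. A corner pixel of a bent
# tubule has 3 neighbors but a single transition run; a true branching has
# >= 3 runs.
branch_counts <- function(sk) {
  img <- matrix(0L, nrow(sk) + 2L, ncol(sk) + 2L)
  img[2:(nrow(sk) + 1L), 2:(ncol(sk) + 1L)] <- sk * 1L
  core_r <- 2:(nrow(img) - 1L); core_c <- 2:(ncol(img) - 1L)
  s <- function(dr, dc) img[core_r + dr, core_c + dc]
  p2 <- s(-1L, 0L); p3 <- s(-1L, 1L); p4 <- s(0L, 1L); p5 <- s(1L, 1L)
  p6 <- s(1L, 0L); p7 <- s(1L, -1L); p8 <- s(0L, -1L); p9 <- s(-1L, -1L)
  a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
    (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
    (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
    (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
  a * sk
}

NB_OFFSETS <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                    c(0, 1), c(1, -1), c(1, 0), c(1, 1))

step_length <- function(p, q) {
  if (p[1] != q[1] && p[2] != q[2]) sqrt(2) else 1
}

#' Binarize a vascular network image
#'
#' Applies the IsoData automatic threshold followed by a morphological
#' opening (1 erosion + 1 dilation) to suppress speckle, the same cleanup
#' used ahead of skeleton analysis.
#'
#' @param img `calibrated_image` of the network (phase contrast or GFP).
#' @param polarity `"bright"` if vessels are brighter than background,
#'   `"dark"` for inverted-contrast input (the image is inverted before
#'   thresholding).
#' @return A `binary_mask`; an all-background mask with a warning for a
#'   constant image.
#' @export
binarize_network <- function(img, polarity = c("bright", "dark")) {
  stopifnot(inherits(img, "calibrated_image"))
  polarity <- match.arg(polarity)
  work <- img
  if (polarity == "dark") {
    work <- calibrated_image(max(img$pixels) - img$pixels, img$channel_role,
                             img$pixel_size_um)
  }
  m <- default_threshold(work)
  if (!any(m$pixels)) return(m)
  morph_clean(m, 1L, 1L)
}

#' Skeletonize a vessel mask and measure its network topology
#'
#' Thins the mask to a 1-px skeleton (Zhang-Suen), identifies junctions
#' (skeleton pixels with >= 3 neighbors, adjacent junction pixels merged
#' into single junction nodes) and endpoints (exactly 1 neighbor), and
#' traces the tubule segments between nodes. Segment lengths use 1 px per
#' axial and sqrt(2) px per diagonal step, scaled by the mask calibration.
#'
#' @param mask A `binary_mask` of the vessel network.
#' @param min_spur_um Terminal (junction-to-endpoint) segments shorter than
#'   this are dropped from the segment list and total length (default 0:
#'   no pruning).
#' @return A `network_skeleton`: `skeleton_mask`, `junctions` (data frame
#'   of merged junction nodes), `endpoints`, `segments` (data frame with
#'   per-segment length and node types) and `total_length_um`.
#' @export
skeletonize_and_measure <- function(mask, min_spur_um = 0) {
  stopifnot(inherits(mask, "binary_mask"))
  ps <- mask$pixel_size_um
  sk <- zhang_suen_skeleton(mask$pixels)
  empty <- function() {
    structure(list(
      skeleton_mask = binary_mask(sk | matrix(FALSE, nrow(sk), ncol(sk)),
                                  ps, provenance = "skeleton"),
      junctions = data.frame(row = numeric(0), col = numeric(0),
                             n_pixels = integer(0)),
      endpoints = data.frame(row = integer(0), col = integer(0)),
      segments = data.frame(length_um = numeric(0), n_px = integer(0),
                            kind = character(0), end1_row = numeric(0),
                            end1_col = numeric(0), end2_row = numeric(0),
                            end2_col = numeric(0)),
      total_length_um = 0, pixel_size_um = ps), class = "network_skeleton")
  }
  if (!any(sk)) return(empty())
  H <- nrow(sk); W <- ncol(sk)
  nb <- neighbor_counts(sk)
  br <- branch_counts(sk)
  jpix <- sk & nb >= 3L & br >= 3L
  epix <- sk & nb == 1L
  # Merge junction pixels into junction nodes. Thinning splits an X-crossing
  # into two nearby 3-neighbor pixels, so clustering uses a 1-px dilation:
  # junction pixels within 2 px of each other form one node.
  jdil <- as.matrix(EBImage::dilate(jpix * 1,
                                    EBImage::makeBrush(3, "box"))) > 0
  jlab_d <- label_components(jdil)
  jlab <- matrix(0L, H, W)
  jlab[jpix] <- jlab_d[jpix]
  # relabel to consecutive ids
  ids <- sort(unique(jlab[jlab > 0L]))
  if (length(ids)) jlab[jpix] <- match(jlab[jpix], ids)
  n_j <- max(jlab)
  # node id per pixel: junction cluster 1..n_j; endpoints n_j+1, ...
  node_id <- matrix(0L, H, W)
  node_id[jpix] <- jlab[jpix]
  eidx <- which(epix, arr.ind = TRUE)
  if (nrow(eidx) > 0L) {
    node_id[epix] <- n_j + seq_len(nrow(eidx))
  }
  is_node <- node_id > 0L
  nbrs_of <- function(p) {
    rr <- p[1] + NB_OFFSETS[, 1]; cc <- p[2] + NB_OFFSETS[, 2]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    out <- cbind(rr[ok], cc[ok])
    out[sk[out], , drop = FALSE]
  }
  visited_chain <- matrix(FALSE, H, W)
  seg_len <- numeric(0); seg_npx <- integer(0); seg_kind <- character(0)
  edge_keys <- character(0)
  node_pixels <- which(is_node, arr.ind = TRUE)
  seg_ends <- matrix(numeric(0), 0, 4)
  add_segment <- function(len_px, n_px, id_a, id_b, pa, pb) {
    kind <- if (id_a <= n_j && id_b <= n_j) "junction-junction"
    else if (id_a > n_j && id_b > n_j) "endpoint-endpoint"
    else "junction-endpoint"
    seg_len <<- c(seg_len, len_px * ps)
    seg_npx <<- c(seg_npx, n_px)
    seg_kind <<- c(seg_kind, kind)
    seg_ends <<- rbind(seg_ends, c(pa[1], pa[2], pb[1], pb[2]))
  }
  for (i in seq_len(nrow(node_pixels))) {
    p <- node_pixels[i, ]
    pid <- node_id[p[1], p[2]]
    for (qrow in seq_len(nrow(nbrs_of(p)))) {
      q <- nbrs_of(p)[qrow, ]
      qid <- node_id[q[1], q[2]]
      if (qid > 0L) {
        # direct node-to-node contact; skip internal cluster adjacency
        if (qid == pid) next
        key <- paste(sort(c((p[2] - 1) * H + p[1], (q[2] - 1) * H + q[1])),
                     collapse = "-")
        if (key %in% edge_keys) next
        edge_keys <- c(edge_keys, key)
        add_segment(step_length(p, q), 0L, pid, qid, p, q)
      } else {
        if (visited_chain[q[1], q[2]]) next
        # walk along the chain until the next node pixel
        len <- step_length(p, q)
        npx <- 1L
        visited_chain[q[1], q[2]] <- TRUE
        prev <- p; cur <- q
        repeat {
          nxt <- nbrs_of(cur)
          nxt <- nxt[!(nxt[, 1] == prev[1] & nxt[, 2] == prev[2]), ,
                     drop = FALSE]
          if (nrow(nxt) == 0L) { # dead end without endpoint flag (isolated)
            add_segment(len, npx, pid, n_j + 10^6L, p, cur)
            break
          }
          if (nrow(nxt) > 1L) {
            # corner pixels may offer a redundant diagonal shortcut; prefer
            # the continuation not adjacent to the previous pixel, then
            # axial steps
            adj_prev <- pmax(abs(nxt[, 1] - prev[1]),
                             abs(nxt[, 2] - prev[2])) <= 1
            diag_step <- nxt[, 1] != cur[1] & nxt[, 2] != cur[2]
            nxt <- nxt[order(adj_prev, diag_step), , drop = FALSE]
          }
          nxt <- nxt[1, ]
          len <- len + step_length(cur, nxt)
          if (is_node[nxt[1], nxt[2]]) {
            end_id <- node_id[nxt[1], nxt[2]]
            # 1-2 chain pixels connecting two pixels of the same merged
            # junction node are part of the node, not a tubule
            if (!(end_id == pid && npx <= 2L)) {
              add_segment(len, npx, pid, end_id, p, nxt)
            }
            break
          }
          visited_chain[nxt[1], nxt[2]] <- TRUE
          npx <- npx + 1L
          prev <- cur; cur <- nxt
        }
      }
    }
  }
  # pure cycles: chain pixels never reached from any node
  remaining <- sk & !is_node & !visited_chain & nb == 2L
  while (any(remaining)) {
    startp <- which(remaining, arr.ind = TRUE)[1, ]
    visited_chain[startp[1], startp[2]] <- TRUE
    remaining[startp[1], startp[2]] <- FALSE
    nn <- nbrs_of(startp)
    len <- 0; npx <- 1L
    prev <- startp; cur <- nn[1, ]
    len <- len + step_length(startp, cur)
    while (!(cur[1] == startp[1] && cur[2] == startp[2])) {
      visited_chain[cur[1], cur[2]] <- TRUE
      remaining[cur[1], cur[2]] <- FALSE
      npx <- npx + 1L
      nxt <- nbrs_of(cur)
      nxt <- nxt[!(nxt[, 1] == prev[1] & nxt[, 2] == prev[2]), , drop = FALSE]
      if (nrow(nxt) == 0L) break
      prev <- cur; cur <- nxt[1, ]
      len <- len + step_length(prev, cur)
    }
    seg_len <- c(seg_len, len * ps)
    seg_npx <- c(seg_npx, npx)
    seg_kind <- c(seg_kind, "cycle")
    seg_ends <- rbind(seg_ends, c(startp[1], startp[2], startp[1], startp[2]))
  }
  segments <- data.frame(length_um = seg_len, n_px = seg_npx,
                         kind = seg_kind,
                         end1_row = seg_ends[, 1], end1_col = seg_ends[, 2],
                         end2_row = seg_ends[, 3], end2_col = seg_ends[, 4])
  if (min_spur_um > 0 && nrow(segments) > 0L) {
    drop <- segments$kind == "junction-endpoint" &
      segments$length_um < min_spur_um
    segments <- segments[!drop, , drop = FALSE]
  }
  jdf <- if (n_j > 0L) {
    do.call(rbind, lapply(seq_len(n_j), function(j) {
      ji <- which(jlab == j, arr.ind = TRUE)
      data.frame(row = mean(ji[, 1]), col = mean(ji[, 2]),
                 n_pixels = nrow(ji))
    }))
  } else {
    data.frame(row = numeric(0), col = numeric(0), n_pixels = integer(0))
  }
  structure(list(
    skeleton_mask = binary_mask(sk, ps, provenance = "skeleton"),
    junctions = jdf,
    endpoints = as.data.frame(eidx),
    segments = segments,
    total_length_um = sum(segments$length_um),
    pixel_size_um = ps), class = "network_skeleton")
}

#' @export
print.network_skeleton <- function(x, ...) {
  cat(sprintf("<network_skeleton> %d junctions, %d endpoints, %d segments, total %.1f um\n",
              nrow(x$junctions), nrow(x$endpoints), nrow(x$segments),
              x$total_length_um))
  invisible(x)
}

#' Per-field-of-view network summary
#'
#' @param skeleton A [skeletonize_and_measure()] result.
#' @param fov_label Field-of-view label for the summary row.
#' @return One-row data frame: `fov_label`, `junctions_per_fov`,
#'   `total_tubule_length_um_per_fov`.
#' @export
network_summary <- function(skeleton, fov_label = "fov1") {
  stopifnot(inherits(skeleton, "network_skeleton"))
  data.frame(fov_label = fov_label,
             junctions_per_fov = nrow(skeleton$junctions),
             total_tubule_length_um_per_fov = skeleton$total_length_um)
}
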