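# Independent oracles used across the suite. Deliberately naive
# implementations, kept separate from the package's own code paths.

# Edit distance by the plain recursion (exponential; short strings only).
lev_recursive <- function(x, y) {
  if (nchar(x) == 0) return(nchar(y))
  if (nchar(y) == 0) return(nchar(x))
  tx <- substr(x, 2, nchar(x))
  ty <- substr(y, 2, nchar(y))
  if (substr(x, 1, 1) == substr(y, 1, 1)) {
    return(lev_recursive(tx, ty))
  }
  1 + min(
    lev_recursive(tx, y),
    lev_recursive(x, ty),
    lev_recursive(tx, ty)
  )
}

hamming1 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) == 1
}

# Brute-force directional UMI clustering: full directed graph, BFS from
# nodes in descending count (ties lexicographic).
brute_directional <- function(umis, counts) {
  ord <- order(-counts, umis)
  umis <- umis[ord]
  counts <- counts[ord]
  m <- length(umis)
  edge <- matrix(FALSE, m, m)
  for (u in seq_len(m)) {
    for (v in seq_len(m)) {
      if (u != v && hamming1(umis[u], umis[v]) &&
        counts[u] >= 2 * counts[v] - 1) {
        edge[u, v] <- TRUE
      }
    }
  }
  cluster <- rep(NA_integer_, m)
  k <- 0
  for (s in seq_len(m)) {
    if (!is.na(cluster[s])) next
    k <- k + 1
    queue <- s
    cluster[s] <- k
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      nxt <- which(edge[u, ] & is.na(cluster))
      cluster[nxt] <- k
      queue <- c(queue, nxt)
    }
  }
  # canonical form: sorted member sets
  sets <- lapply(split(umis, cluster), sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}

# Brute-force Delaunay edges: (i, j) is an edge iff some triangle (i, j, k)
# has an empty circumcircle (points assumed in general position).
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
    (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
    (cx^2 + cy^2) * (bx - ax)) / d
  list(x = ux, y = uy, r = sqrt((ax - ux)^2 + (ay - uy)^2))
}

brute_delaunay_edges <- function(xy) {
  n <- nrow(xy)
  edges <- character(0)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        cc <- circumcircle(xy[i, ], xy[j, ], xy[k, ])
        if (is.null(cc)) next
        others <- setdiff(seq_len(n), c(i, j, k))
        dist2 <- sqrt((xy[others, 1] - cc$x)^2 + (xy[others, 2] - cc$y)^2)
        if (all(dist2 > cc$r * (1 + 1e-9))) {
          edges <- c(
            edges,
            paste(i, j, sep = "-"), paste(i, k, sep = "-"),
            paste(j, k, sep = "-")
          )
        }
      }
    }
  }
  sort(unique(edges))
}

graph_edge_keys <- function(graph) {
  idx <- match(c(graph$edges$from, graph$edges$to), graph$nodes$barcode)
  m <- matrix(idx, ncol = 2)
  sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "-"))
}

random_peptides <- function(n, max_len, alphabet = c("A", "C", "S", "T")) {
  vapply(seq_len(n), function(i) {
    paste(
      sample(alphabet, sample(0:max_len, 1), replace = TRUE),
      collapse = ""
    )
  }, character(1))
}

# Small spot table fixtures for hand-checked geometry.
triangle_spots <- function() {
  tibble::tibble(
    barcode = c("S1", "S2", "S3"),
    x = c(0, 1, 0.5), y = c(0, 0, 1),
    in_tissue = TRUE, n_cells = 2L, total_umis = 100L
  )
}

square_spots <- function() {
  tibble::tibble(
    barcode = paste0("S", 1:4),
    x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
    in_tissue = TRUE, n_cells = 2L, total_umis = 100L
  )
}

hexagon_spots <- function() {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  tibble::tibble(
    barcode = c("C0", paste0("H", 1:6)),
    x = c(0, cos(ang)), y = c(0, sin(ang)),
    in_tissue = TRUE, n_cells = 2L, total_umis = 100L
  )
}

# A minimal clones object without running the read pipeline.
make_clones <- function(df) {
  # df: tibble(clone_id, locus, cdr3_aa, barcode, umi_count)
  records <- dplyr::mutate(df,
    v_call = "V1", j_call = "J1",
    v_identity = 1, j_identity = 1
  )
  cluster_cdr3(records, min_dist = 2)
}
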