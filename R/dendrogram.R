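#' Agglomerative dendrogram from a similarity matrix
#'
#' Clusters species by their band-profile similarity. Similarities are
#' converted to distances (`100 - SI` on the percent scale, `1 - r` on the
#' correlation scale) and clustered agglomeratively. The default UPGMA
#' (average) linkage yields an ultrametric tree whose merge heights are
#' non-decreasing from leaves to root; `single` and `complete` linkage are
#' available. Ties between equally close pairs are broken by merging the
#' lexicographically smallest label pair, so the result is deterministic.
#'
#' Node heights follow the merge-distance convention: the height of an
#' internal node is the cluster distance at which its children merged, and
#' the height at which two leaves first share a cluster reproduces their
#' input distance exactly for ultrametric inputs.
#'
#' @param s a `similarity_matrix` (see [pairwise_si_matrix()]) or a square
#'   symmetric distance matrix with `dimnames` (passed with
#'   `is_distance = TRUE`).
#' @param linkage one of `"upgma"` (default), `"single"`, `"complete"`.
#' @param is_distance set `TRUE` when `s` is already a distance matrix.
#' @return an object of class `band_dendrogram`: list with `merge`,
#'   `height`, `labels`, `linkage` (hclust-style merge encoding).
#' @export
build_dendrogram <- function(s, linkage = c("upgma", "single", "complete"),
                             is_distance = FALSE) {
  linkage <- match.arg(linkage)
  d <- if (is_distance) as.matrix(s) else similarity_to_distance(s)
  labels <- rownames(d)
  n <- nrow(d)
  if (is.null(labels) || n < 2) stop("need a labelled matrix with >= 2 rows")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("similarity/distance matrix must be symmetric")
  }
  diag(d) <- 0

  # active clusters: id (negative leaf index / positive merge index),
  # size, smallest member label (for the deterministic tie rule)
  act_id <- -seq_len(n)
  act_size <- rep(1L, n)
  act_min <- labels
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    m <- length(act_id)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        key <- sort(c(act_min[i], act_min[j]))
        if (is.null(best) || D[i, j] < best$d - 1e-12 ||
            (abs(D[i, j] - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = D[i, j], key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(act_id[i], act_id[j]))
    height[step] <- best$d

    ni <- act_size[i]; nj <- act_size[j]
    newrow <- switch(linkage,
      upgma    = (ni * D[i, ] + nj * D[j, ]) / (ni + nj),
      single   = pmin(D[i, ], D[j, ]),
      complete = pmax(D[i, ], D[j, ]))
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    act_id <- c(act_id[keep], step)
    act_size <- c(act_size[keep], ni + nj)
    act_min <- c(act_min[keep], min(best$key))
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage),
            class = "band_dendrogram")
}

#' @export
print.band_dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram (%s linkage), %d leaves: %s\n", x$linkage,
              length(x$labels), paste(x$labels, collapse = ", ")))
  cat("merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  invisible(x)
}

.newick_label <- function(lab) {
  if (grepl("[][()[:space:],;:'\"]", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else lab
}

#' Serialize a dendrogram to a Newick string
#'
#' Branch lengths are node-height differences (leaves sit at height 0),
#' so a two-leaf cherry merged at height h is written `(A:h,B:h);`.
#' Labels with spaces or Newick metacharacters are single-quoted.
#'
#' @param t a `band_dendrogram`.
#' @return a single Newick string terminated by `;`.
#' @export
newick_string <- function(t) {
  rec <- function(id) {
    if (id < 0) {
      list(str = .newick_label(t$labels[-id]), h = 0, lead = t$labels[-id])
    } else {
      a <- rec(t$merge[id, 1]); b <- rec(t$merge[id, 2])
      if (b$lead < a$lead) { tmp <- a; a <- b; b <- tmp }
      h <- t$height[id]
      list(str = sprintf("(%s:%s,%s:%s)", a$str, format(h - a$h, trim = TRUE),
                         b$str, format(h - b$h, trim = TRUE)),
           h = h, lead = a$lead)
    }
  }
  paste0(rec(nrow(t$merge))$str, ";")
}

#' Write a dendrogram as a Newick file
#'
#' @param t a `band_dendrogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(t, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open path for writing: ", path, call. = FALSE)
  })
  on.exit(close(con))
  writeLines(newick_string(t), con)
  invisible(path)
}

#' Cophenetic merge heights of a dendrogram
#'
#' Height at which each pair of leaves first joins a common cluster. For
#' UPGMA trees built from ultrametric distances this reproduces the input
#' distances exactly.
#'
#' @param t a `band_dendrogram`.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
cophenetic_heights <- function(t) {
  n <- length(t$labels)
  members <- vector("list", n - 1)
  out <- matrix(0, n, n, dimnames = list(t$labels, t$labels))
  getm <- function(id) if (id < 0) -id else members[[id]]
  for (k in seq_len(n - 1)) {
    a <- getm(t$merge[k, 1]); b <- getm(t$merge[k, 2])
    out[a, b] <- out[b, a] <- t$height[k]
    members[[k]] <- c(a, b)
  }
  out
}

#' Convert a dendrogram to an ape "phylo" tree
#'
#' @param t a `band_dendrogram`.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
as_phylo <- function(t) {
  ape::read.tree(text = newick_string(t))
}
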