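#' Generate a synthetic cell monolayer
#'
#' Places hard discs by random sequential adsorption (RSA) until the disc-area
#' fraction reaches `target_confluency`: candidate centres are drawn uniformly
#' (discs kept fully inside the field) and rejected if they overlap an
#' accepted disc by more than `overlap_tolerance` of the summed radii.
#' Diameters are drawn from a normal distribution truncated at a small
#' positive floor. Each cell is independently labelled `transfected` with
#' probability `transfected_fraction`, and exactly `n_illuminated` transfected
#' cells are marked for optogenetic activation.
#'
#' Coordinates are in micrometres with the origin at the field corner and y
#' increasing downward (image convention).
#'
#' @param config a [simulation_config()].
#' @return a `cell_table`: data frame with columns `id`, `x`, `y`,
#'   `diameter` (um), `population` (`"transfected"`/`"bystander"`),
#'   `illuminated` (logical); attributes `field_size` and `config`.
#' @examples
#' cells <- generate_monolayer(simulation_config(field_size = 200, seed = 7))
#' sum(pi * (cells$diameter / 2)^2) / 200^2  # realized confluency
#' @export
generate_monolayer <- function(config) {
  validate_simulation_config(config)
  L <- config$field_size
  target <- config$target_confluency
  dmin <- max(1e-3, config$diameter_mean - 4 * config$diameter_sd)
  withr::with_seed(config$seed, {
    n_exp <- ceiling(target * L^2 / (pi * (config$diameter_mean / 2)^2))
    max_attempts <- 400L * n_exp + 1000L
    xs <- ys <- rad <- numeric(0)
    area <- 0
    attempts <- 0L
    while (area / L^2 < target && attempts < max_attempts) {
      attempts <- attempts + 1L
      d <- rtruncnorm(1L, config$diameter_mean, config$diameter_sd,
                      lower = dmin)
      r <- d / 2
      if (2 * r > L) next
      x <- runif(1L, r, L - r)
      y <- runif(1L, r, L - r)
      if (length(xs)) {
        lim <- (1 - config$overlap_tolerance) * (r + rad)
        if (any((x - xs)^2 + (y - ys)^2 < lim^2)) next
      }
      xs <- c(xs, x); ys <- c(ys, y); rad <- c(rad, r)
      area <- area + pi * r^2
    }
    realized <- area / L^2
    if (realized < target - 0.05)
      stopf(paste0("packing failed: achieved confluency %.3f after %d ",
                   "attempts (target %.3f)"), realized, attempts, target)
    n <- length(xs)
    transfected <- runif(n) < config$transfected_fraction
    n_tr <- sum(transfected)
    if (config$n_illuminated > n_tr)
      stopf("n_illuminated (%d) exceeds number of transfected cells (%d)",
            config$n_illuminated, n_tr)
    illuminated <- rep(FALSE, n)
    if (config$n_illuminated > 0)
      illuminated[resample(which(transfected), config$n_illuminated)] <- TRUE
    cells <- data.frame(
      id = seq_len(n),
      x = xs, y = ys,
      diameter = 2 * rad,
      population = ifelse(transfected, "transfected", "bystander"),
      illuminated = illuminated,
      stringsAsFactors = FALSE
    )
    attr(cells, "field_size") <- L
    attr(cells, "config") <- config
    class(cells) <- c("cell_table", "data.frame")
    cells
  })
}

#' Build the cell-cell contact graph
#'
#' Two cells are in contact when their centroid distance does not exceed
#' `kappa * (diameter_i + diameter_j) / 2`. With `kappa = 1` this is exact
#' disc tangency; the default 1.5 reflects the reach of adherent cell
#' footprints (lamellipodia, spread edges) beyond the nominal disc.
#'
#' @param cells a `cell_table` (see [generate_monolayer()]), or any data frame
#'   with `id`, `x`, `y`, `diameter`.
#' @param kappa dimensionless contact scale, > 0.
#' @return a `contact_graph`: list with `edges` (data frame `from`, `to`, cell
#'   ids, `from < to`), `kappa`, and `ids`.
#' @examples
#' cells <- data.frame(id = 1:2, x = c(0, 20), y = c(0, 0), diameter = 23)
#' build_contact_graph(cells, kappa = 1)$edges
#' @export
build_contact_graph <- function(cells, kappa = 1.5) {
  check_pos(kappa, "kappa")
  n <- nrow(cells)
  if (n < 2L) {
    edges <- data.frame(from = integer(0), to = integer(0))
  } else {
    dx <- outer(cells$x, cells$x, "-")
    dy <- outer(cells$y, cells$y, "-")
    thr <- kappa * outer(cells$diameter, cells$diameter, "+") / 2
    adj <- (dx^2 + dy^2) <= thr^2
    adj[!upper.tri(adj)] <- FALSE
    idx <- which(adj, arr.ind = TRUE)
    edges <- data.frame(from = cells$id[idx[, 1L]], to = cells$id[idx[, 2L]])
  }
  structure(list(edges = edges, kappa = kappa, ids = cells$id),
            class = "contact_graph")
}

# adjacency list in row-index space of `ids`
adjacency_list <- function(graph, ids = graph$ids) {
  pos <- match(graph$ids, ids)
  if (anyNA(match(c(graph$edges$from, graph$edges$to), ids)))
    stopf("contact graph references cell ids absent from the cell table")
  nbrs <- vector("list", length(ids))
  for (k in seq_along(nbrs)) nbrs[[k]] <- integer(0)
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, ids)
    j <- match(graph$edges$to, ids)
    for (e in seq_along(i)) {
      nbrs[[i[e]]] <- c(nbrs[[i[e]]], j[e])
      nbrs[[j[e]]] <- c(nbrs[[j[e]]], i[e])
    }
  }
  nbrs
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d cells, %d edges (kappa = %g)\n",
              length(x$ids), nrow(x$edges), x$kappa))
  invisible(x)
}

#' Read and write cell tables and contact graphs as CSV
#'
#' `write_cell_table()`/`read_cell_table()` round-trip the `cell_table`
#' columns plus a `field_size` comment-free sidecar column; the contact graph
#' is a two-column edge list.
#'
#' @param cells a `cell_table`.
#' @param graph a `contact_graph`.
#' @param path CSV path.
#' @param field_size field side in micrometres (stored as an attribute on
#'   read).
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_cell_table <- function(cells, path) {
  df <- as.data.frame(cells)
  df$field_size <- attr(cells, "field_size") %||% NA_real_
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  fs <- if ("field_size" %in% names(df)) df$field_size[1L] else NA_real_
  df$field_size <- NULL
  attr(df, "field_size") <- fs
  class(df) <- c("cell_table", "data.frame")
  df
}

#' @rdname write_cell_table
#' @export
write_edge_list <- function(graph, path) {
  write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @param ids cell ids the graph is defined over (defaults to ids occurring in
#'   the edge list).
#' @param kappa contact scale recorded on the object.
#' @export
read_edge_list <- function(path, ids = NULL, kappa = NA_real_) {
  edges <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges)))
    stopf("edge list must have columns `from` and `to`")
  if (is.null(ids)) ids <- sort(unique(c(edges$from, edges$to)))
  structure(list(edges = edges[, c("from", "to")], kappa = kappa, ids = ids),
            class = "contact_graph")
}
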