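#' Construct an ego network
#'
#' An ego network holds one participant's elicited personal network at one
#' timepoint: an alter attribute table and a symmetric binary alter-alter
#' tie matrix.  The ego (index person) is not a row of either: by survey
#' construction the ego is tied to every alter, so the ego's ties carry no
#' information and only alter-alter ties are stored.
#'
#' @param participant_id Scalar identifier.
#' @param timepoint `"prepandemic"` or `"pandemic"`.
#' @param alters A data frame with one row per alter.  Recognized columns:
#'   `alter_id`, `relationship`, `age`, `sex`, `race`, `contact_freq`,
#'   `years_known`, `distance_gt_15mi`, `drinks`, `smokes`, `nonexerciser`,
#'   `bad_diet`, `negative_influence`.  All attribute columns are optional
#'   and may contain missing values.
#' @param ties A square logical (or 0/1) matrix over the alters, in alter
#'   row order; symmetric with a zero diagonal.  Defaults to no ties.
#' @return An object of class `ego_network`.
#' @export
#' @examples
#' net <- ego_network("p1", alters = tibble::tibble(
#'   alter_id = c("a", "b", "c"),
#'   relationship = c("spouse", "friend", "parent")
#' ), ties = matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3))
#' network_size(net)
ego_network <- function(participant_id, timepoint = "pandemic", alters,
                        ties = NULL) {
  alters <- tibble::as_tibble(alters)
  if (!"alter_id" %in% names(alters)) {
    alters$alter_id <- as.character(seq_len(nrow(alters)))
  }
  alters$alter_id <- as.character(alters$alter_id)
  n <- nrow(alters)
  if (is.null(ties)) ties <- matrix(FALSE, n, n)
  ties <- matrix(as.logical(ties), nrow(ties), ncol(ties))
  dimnames(ties) <- list(alters$alter_id, alters$alter_id)
  out <- structure(
    list(participant_id = as.character(participant_id),
         timepoint = as.character(timepoint),
         alters = alters, ties = ties),
    class = "ego_network"
  )
  validate_ego_network(out)
  out
}

#' Validate an ego network
#'
#' Checks the structural invariants: unique alter identifiers, a square
#' symmetric logical tie matrix with a zero (FALSE) diagonal whose
#' dimension equals the number of alters, and non-negative `age` and
#' `years_known` where present.
#'
#' @param x An `ego_network`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_ego_network <- function(x) {
  stopifnot(inherits(x, "ego_network"))
  a <- x$alters
  n <- nrow(a)
  if (anyDuplicated(a$alter_id)) {
    stop("duplicate alter_id within a network: ",
         paste(unique(a$alter_id[duplicated(a$alter_id)]), collapse = ", "))
  }
  t <- x$ties
  if (!is.matrix(t) || nrow(t) != n || ncol(t) != n) {
    stop("tie matrix must be square with dimension equal to the number of alters")
  }
  if (any(is.na(t))) stop("tie matrix must not contain missing values")
  if (n > 0 && any(diag(t))) stop("tie matrix diagonal must be empty (no self-ties)")
  if (!isTRUE(all(t == base::t(t)))) {
    bad <- which(t != base::t(t), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("tie matrix is not symmetric for pair(s): ",
         paste(sprintf("(%s,%s)", rownames(t)[bad[, 1]],
                       colnames(t)[bad[, 2]]), collapse = ", "))
  }
  if (!is.null(a[["age"]]) && any(a[["age"]] < 0, na.rm = TRUE)) {
    stop("alter age must be non-negative")
  }
  if (!is.null(a[["years_known"]]) && any(a[["years_known"]] < 0, na.rm = TRUE)) {
    stop("years_known must be non-negative")
  }
  invisible(x)
}

#' Number of alters in an ego network
#'
#' @param net An `ego_network`.
#' @return Integer network size (the ego is excluded by construction).
#' @export
network_size <- function(net) nrow(net$alters)

#' @export
print.ego_network <- function(x, ...) {
  n <- network_size(x)
  t <- sum(x$ties) / 2
  cat(sprintf("<ego_network> participant %s (%s): %d alter%s, %d alter-alter tie%s\n",
              x$participant_id, x$timepoint, n, if (n == 1) "" else "s",
              t, if (t == 1) "" else "s"))
  invisible(x)
}

#' Convert an ego network to an igraph graph
#'
#' Builds the full undirected graph on ego plus alters: the ego vertex
#' (named `"ego"`) is tied to every alter, and alter-alter edges come from
#' the tie matrix.  Alter attribute columns become vertex attributes.
#'
#' @param net An `ego_network`.
#' @param include_ego Include the ego vertex and its spokes (default TRUE).
#' @return An `igraph` object.
#' @export
as_igraph <- function(net, include_ego = TRUE) {
  n <- network_size(net)
  ids <- net$alters$alter_id
  el <- which(net$ties & upper.tri(net$ties), arr.ind = TRUE)
  edges <- cbind(ids[el[, 1]], ids[el[, 2]])
  if (include_ego) {
    edges <- rbind(cbind(rep("ego", n), ids), edges)
    verts <- tibble::tibble(name = c("ego", ids))
  } else {
    verts <- tibble::tibble(name = ids)
  }
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                     vertices = as.data.frame(verts))
  for (col in setdiff(names(net$alters), "alter_id")) {
    vals <- net$alters[[col]]
    if (include_ego) vals <- c(NA, vals)
    g <- igraph::set_vertex_attr(g, col, value = vals)
  }
  g
}

#' Export an ego network to GraphML
#'
#' Writes the ego + alter graph (see [as_igraph()]) in GraphML format for
#' use in external network tools.
#'
#' @param net An `ego_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Build a symmetric tie matrix from index pairs
#'
#' Convenience constructor for the alter-alter tie matrix: takes the
#' network size and a list of index pairs and returns the symmetric
#' logical matrix with those ties set in both directions.
#'
#' @param n Number of alters.
#' @param pairs List of length-2 integer vectors (alter indices).
#' @return An `n` by `n` logical matrix.
#' @export
#' @examples
#' tie_matrix(3, list(c(1, 2), c(2, 3)))
tie_matrix <- function(n, pairs = list()) {
  m <- matrix(FALSE, n, n)
  for (p in pairs) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
}
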