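#' The 15 CLIPST region labels
#'
#' Node labels of the corticolimbic-insular-striatal-pallidal-thalamic
#' (CLIPST) circuitry model of mood regulation, in canonical grid order.
#'
#' @return Character vector of 15 region labels.
#' @export
#' @examples
#' clipst_nodes()
clipst_nodes <- function() {
  c("dmPFC", "dlPFC", "omPFC", "vmPFC", "vlPFC", "Hypothalamus", "ACC",
    "PCC", "Insula", "Amygdala", "Hippocampus", "Thalamus", "NAcc",
    "Putamen", "Caudate")
}

# The 39 numbered connections of interest of the CLIPST model.
clipst_coi_edges <- function() {
  tibble::tribble(
    ~index, ~region_i,      ~region_j,
    1L,  "dmPFC", "dlPFC",
    2L,  "dmPFC", "omPFC",
    3L,  "dmPFC", "vmPFC",
    4L,  "dmPFC", "vlPFC",
    5L,  "dmPFC", "PCC",
    6L,  "dlPFC", "omPFC",
    7L,  "dlPFC", "vmPFC",
    8L,  "dlPFC", "vlPFC",
    9L,  "dlPFC", "ACC",
    10L, "omPFC", "vmPFC",
    11L, "omPFC", "vlPFC",
    12L, "omPFC", "Hypothalamus",
    13L, "omPFC", "ACC",
    14L, "omPFC", "PCC",
    15L, "omPFC", "Insula",
    16L, "omPFC", "Hippocampus",
    17L, "omPFC", "Thalamus",
    18L, "omPFC", "NAcc",
    19L, "vmPFC", "vlPFC",
    20L, "vmPFC", "Hypothalamus",
    21L, "vmPFC", "ACC",
    22L, "vmPFC", "PCC",
    23L, "vmPFC", "Insula",
    24L, "vmPFC", "Hippocampus",
    25L, "vmPFC", "Thalamus",
    26L, "vmPFC", "NAcc",
    27L, "vlPFC", "Hypothalamus",
    28L, "vlPFC", "ACC",
    29L, "vlPFC", "Insula",
    30L, "vlPFC", "Hippocampus",
    31L, "vlPFC", "Thalamus",
    32L, "vlPFC", "NAcc",
    33L, "Hypothalamus", "Insula",
    34L, "Hypothalamus", "Amygdala",
    35L, "ACC", "Insula",
    36L, "ACC", "Amygdala",
    37L, "ACC", "Hippocampus",
    38L, "ACC", "Thalamus",
    39L, "Amygdala", "Thalamus"
  )
}

#' All unordered region pairs for a node set
#'
#' @param nodes Character vector of region labels.
#' @return Tibble with columns `region_i`, `region_j`, `connection` listing
#'   all `choose(K, 2)` unordered pairs in canonical (upper-triangle) order.
#' @export
all_connections <- function(nodes = clipst_nodes()) {
  idx <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble(
    region_i = nodes[idx[, "row"]],
    region_j = nodes[idx[, "col"]],
    connection = paste0(nodes[idx[, "row"]], "--", nodes[idx[, "col"]])
  )
}

#' Construct a connection-of-interest grid
#'
#' A COI grid partitions all unordered region pairs over a node set into
#' connections of interest (hypothesized by a disease model to carry drug
#' effects) and the complement. The shipped default ([clipst_coi_grid()])
#' encodes the 39 CLIPST connections of interest over 15 regions
#' (105 pairs total).
#'
#' @param coi_edges Data frame with columns `region_i`, `region_j` (and
#'   optionally `index`) listing the connections of interest.
#' @param nodes Character vector of region labels.
#' @return An object of class `coi_grid`: a list with elements `nodes`,
#'   `coi` (tibble of COI edges with canonical `connection` keys), and
#'   `all` (tibble of all pairs with logical column `is_coi`).
#' @export
coi_grid <- function(coi_edges, nodes = clipst_nodes()) {
  if (anyDuplicated(nodes)) {
    abort("Region labels must be unique.", class = "coinet_bad_argument")
  }
  coi_edges <- as_tibble(coi_edges)
  if (nrow(coi_edges)) {
    unknown <- setdiff(c(coi_edges$region_i, coi_edges$region_j), nodes)
    if (length(unknown)) {
      abort(paste0("Unknown region label(s) in COI definition: ",
                   paste(unique(unknown), collapse = ", ")),
            class = "coinet_unknown_node")
    }
    if (any(coi_edges$region_i == coi_edges$region_j)) {
      abort("COI definition contains a self-pair.", class = "coinet_bad_grid")
    }
    key <- connection_key(coi_edges$region_i, coi_edges$region_j, nodes)
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      abort(paste0("Duplicate COI pair(s): ", paste(dup, collapse = ", ")),
            class = "coinet_bad_grid")
    }
    coi_edges$connection <- key
  } else {
    coi_edges <- tibble(region_i = character(), region_j = character(),
                        connection = character())
  }
  all <- all_connections(nodes)
  all$is_coi <- all$connection %in% coi_edges$connection
  if (!"index" %in% names(coi_edges) && nrow(coi_edges)) {
    coi_edges$index <- seq_len(nrow(coi_edges))
  }
  structure(
    list(nodes = nodes,
         coi = dplyr::relocate(coi_edges, dplyr::any_of("index")),
         all = all),
    class = "coi_grid"
  )
}

#' The shipped CLIPST connection-of-interest grid
#'
#' Reproduces the published 15 x 15 grid: 39 numbered connections of
#' interest, 66 remaining pairs, 105 pairs in total.
#'
#' @return A [coi_grid()] object.
#' @export
#' @examples
#' g <- clipst_coi_grid()
#' sum(g$all$is_coi)   # 39
#' sum(!g$all$is_coi)  # 66
clipst_coi_grid <- function() {
  coi_grid(clipst_coi_edges(), clipst_nodes())
}

#' Read a COI grid definition from JSON or YAML
#'
#' The file must contain a `nodes` list and a `coi` list of records with
#' `region_i`, `region_j` and optionally `index` fields. A definition file
#' for the shipped CLIPST grid is installed at
#' `system.file("extdata", "clipst_coi_grid.json", package = "coinet")`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [coi_grid()] object.
#' @export
load_coi_grid <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("COI grid file not found: ", path), class = "coinet_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  def <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    abort("COI grid file must be .json, .yaml or .yml.", class = "coinet_io_error")
  )
  if (is.null(def$nodes)) {
    abort("COI grid definition lacks a `nodes` entry.", class = "coinet_bad_grid")
  }
  coi <- def$coi
  if (is.null(coi)) {
    coi <- tibble(region_i = character(), region_j = character())
  } else if (!is.data.frame(coi)) {
    coi <- dplyr::bind_rows(lapply(coi, as_tibble))
  }
  if (!is.null(def$n_coi) && nrow(coi) != def$n_coi) {
    abort(sprintf("COI grid declares %d connections but lists %d.",
                  def$n_coi, nrow(coi)), class = "coinet_bad_grid")
  }
  coi_grid(coi, unlist(def$nodes))
}

#' Write a COI grid definition to JSON
#'
#' @param grid A [coi_grid()] object.
#' @param path Output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
write_coi_grid <- function(grid, path) {
  stopifnot(inherits(grid, "coi_grid"))
  def <- list(
    nodes = grid$nodes,
    n_coi = nrow(grid$coi),
    coi = grid$coi[, intersect(c("index", "region_i", "region_j"), names(grid$coi))]
  )
  jsonlite::write_json(def, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.coi_grid <- function(x, ...) {
  cat(sprintf("<coi_grid> %d regions, %d pairs: %d connections of interest, %d others\n",
              length(x$nodes), nrow(x$all), sum(x$all$is_coi), sum(!x$all$is_coi)))
  invisible(x)
}

#' @export
as_tibble.coi_grid <- function(x, ...) x$all

#' Render a COI grid as a square annotation matrix
#'
#' Produces the upper-triangle grid layout used to publish the model: cells
#' carry the COI index (as character) for connections of interest, `""`
#' elsewhere. Optionally marks significant connections with `"*"` appended.
#'
#' @param grid A [coi_grid()] object.
#' @param significant Optional character vector of canonical connection keys
#'   (`"a--b"`) to mark.
#' @return A K x K character matrix with region dimnames.
#' @export
render_coi_grid <- function(grid, significant = NULL) {
  stopifnot(inherits(grid, "coi_grid"))
  k <- length(grid$nodes)
  m <- matrix("", k, k, dimnames = list(grid$nodes, grid$nodes))
  for (row in seq_len(nrow(grid$coi))) {
    i <- match(grid$coi$region_i[row], grid$nodes)
    j <- match(grid$coi$region_j[row], grid$nodes)
    lab <- if ("index" %in% names(grid$coi)) as.character(grid$coi$index[row]) else "x"
    m[min(i, j), max(i, j)] <- lab
  }
  if (!is.null(significant)) {
    hit <- grid$all[grid$all$connection %in% significant, ]
    for (row in seq_len(nrow(hit))) {
      i <- match(hit$region_i[row], grid$nodes)
      j <- match(hit$region_j[row], grid$nodes)
      m[min(i, j), max(i, j)] <- paste0(m[min(i, j), max(i, j)], "*")
    }
  }
  m
}
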