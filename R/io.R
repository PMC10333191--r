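# Delimited-text readers and writers for every interchange type. Text is
# the canonical format throughout; every table carries explicit id columns
# so external 1-based/0-based conventions cannot corrupt joins.

#' Write / read a vertex x time series matrix (TSV)
#'
#' @param ts Vertex x time numeric matrix.
#' @param path File path.
#' @return `read_timeseries` returns the matrix.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(is.matrix(ts))
  dt <- data.table::data.table(vertex = seq_len(nrow(ts)))
  dt <- cbind(dt, data.table::as.data.table(ts))
  data.table::setnames(dt, c("vertex", paste0("t", seq_len(ncol(ts)))))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  if (names(dt)[1] != "vertex") {
    stop(path, ": first column must be 'vertex'")
  }
  m <- as.matrix(dt[, -1])
  if (anyNA(m) || !is.numeric(m)) {
    bad <- which(!stats::complete.cases(m))
    stop(path, ": non-numeric or missing values at rows ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (ncol(m) < 2L) stop(path, ": need at least 2 timepoints")
  dimnames(m) <- NULL
  m
}

subject_table_required <- c("subject_id", "group", "age", "sex",
                            "head_motion")

#' Write / read the subject table (CSV)
#'
#' Required columns: subject_id, group, age, sex, head_motion; clinical and
#' cognitive columns are optional. Factors are restored on read.
#'
#' @param table Subject table data.frame.
#' @param path File path.
#' @return `read_subject_table` returns the data.frame.
#' @export
write_subject_table <- function(table, path) {
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- as.data.frame(data.table::fread(path))
  missing <- setdiff(subject_table_required, names(dt))
  if (length(missing)) {
    stop(path, ": missing required columns: ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(dt$age))) stop(path, ": non-finite age values")
  dt$group <- factor(dt$group, levels = c("control", "patient"))
  if (anyNA(dt$group)) stop(path, ": group must be control/patient")
  dt$sex <- factor(dt$sex, levels = c("male", "female"))
  if ("aed" %in% names(dt)) {
    dt$aed <- factor(dt$aed, levels = c("naive", "medication"))
  }
  dt
}

#' Write / read a parcel x gene expression matrix (TSV)
#'
#' Parcel rows with a `parcel_id` column, gene identifiers as the header.
#'
#' @param expr Parcel x gene numeric matrix with dimnames.
#' @param path File path.
#' @return `read_expression` returns the matrix.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  dt <- data.table::data.table(parcel_id = rownames(expr) %||%
                                 paste0("parcel", seq_len(nrow(expr))))
  dt <- cbind(dt, data.table::as.data.table(expr))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  if (names(dt)[1] != "parcel_id") {
    stop(path, ": first column must be 'parcel_id'")
  }
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$parcel_id
  if (anyNA(m)) {
    stop(path, ": expression matrix contains missing values")
  }
  m
}

#' Write / read gene set collections (GMT format)
#'
#' One set per line: name, description, then gene ids, tab separated.
#'
#' @param sets A [gene_set_collection()].
#' @param path File path.
#' @param background Background universe for `read_gene_sets` (default:
#'   union of all sets).
#' @return `read_gene_sets` returns a [gene_set_collection()].
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(nm) {
    paste(c(nm, "na", sets$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(path, background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop(path, ": malformed GMT lines (need name, description, >=1 gene): ",
         paste(short, collapse = ", "))
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  gene_set_collection(sets,
                      background %||% unique(unlist(sets, use.names = FALSE)))
}

#' Write / read a surface mesh as two CSV tables
#'
#' `<prefix>_vertices.csv` holds vertex id, coordinates, community, parcel
#' and hemisphere; `<prefix>_faces.csv` holds the triangle index triplets.
#'
#' @param mesh A `surface_mesh`.
#' @param prefix Path prefix for the two files.
#' @return `read_mesh` returns the `surface_mesh`.
#' @export
write_mesh <- function(mesh, prefix) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- data.frame(vertex = seq_len(nrow(mesh$vertices)),
                  x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                  z = mesh$vertices[, 3], community = mesh$community,
                  parcel = mesh$parcel, hemisphere = mesh$hemisphere)
  data.table::fwrite(v, paste0(prefix, "_vertices.csv"))
  f <- data.frame(v1 = mesh$faces[, 1], v2 = mesh$faces[, 2],
                  v3 = mesh$faces[, 3])
  data.table::fwrite(f, paste0(prefix, "_faces.csv"))
  invisible(prefix)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(prefix) {
  vp <- paste0(prefix, "_vertices.csv")
  fp <- paste0(prefix, "_faces.csv")
  for (p in c(vp, fp)) if (!file.exists(p)) stop("file not found: ", p)
  v <- as.data.frame(data.table::fread(vp))
  f <- as.data.frame(data.table::fread(fp))
  need <- c("vertex", "x", "y", "z", "community", "parcel", "hemisphere")
  missing <- setdiff(need, names(v))
  if (length(missing)) {
    stop(vp, ": missing columns: ", paste(missing, collapse = ", "))
  }
  mesh <- structure(list(
    vertices = as.matrix(v[order(v$vertex), c("x", "y", "z")]),
    faces = as.matrix(f), community = v$community[order(v$vertex)],
    parcel = v$parcel[order(v$vertex)],
    hemisphere = v$hemisphere[order(v$vertex)],
    n_communities = length(unique(v$community)),
    n_parcels = length(unique(v$parcel))
  ), class = "surface_mesh")
  dimnames(mesh$vertices) <- NULL
  dimnames(mesh$faces) <- NULL
  validate_mesh(mesh)
  mesh
}

#' Write / read a stat map (CSV)
#'
#' @param map A `stat_map`.
#' @param path File path.
#' @return `read_stat_map` returns the data.frame (attributes `contrast`
#'   and `df` restored from the header comment are not preserved; the CSV
#'   is the portable record of the numbers).
#' @export
write_stat_map <- function(map, path) {
  data.table::fwrite(as.data.frame(map), path)
  invisible(path)
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.frame(data.table::fread(path))
}

#' Write / read ground truth (JSON)
#'
#' @param truth A [ground_truth()].
#' @param path File path.
#' @return `read_ground_truth` returns the [ground_truth()].
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ground_truth, x[names(x) %in% names(formals(ground_truth))])
}
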