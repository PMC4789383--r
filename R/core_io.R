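#' Construct a validated regional time-course matrix
#'
#' @param values numeric matrix, `L` rows (time points) by `N` columns
#'   (regions).
#' @param region_ids optional character vector of `N` region labels; defaults
#'   to column names or generated labels `r001...rNNN`.
#' @param subject_id subject identifier carried through the pipeline.
#' @param check_variance reject constant columns (default).  Windowed
#'   subseries skip this check at construction; [pearson_correlation()]
#'   re-checks within each window and names the subject and window instead.
#' @return A `timecourse_matrix`: the numeric matrix with region labels as
#'   column names and attribute `subject_id`.
#' @details Validation enforces `L >= 3`, `N >= 2`, no missing values and
#'   nonzero variance in every column (a constant regional signal has no
#'   defined Pearson correlation and is rejected with the offending column
#'   named).
#' @export
timecourse_matrix <- function(values, region_ids = NULL, subject_id = "subject",
                              check_variance = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("time courses must be a numeric matrix", call. = FALSE)
  L <- nrow(values); N <- ncol(values)
  if (L < 3) stop(sprintf("need at least 3 time points, got %d rows", L),
                  call. = FALSE)
  if (N < 2) stop(sprintf("need at least 2 regions, got %d columns", N),
                  call. = FALSE)
  if (is.null(region_ids)) {
    region_ids <- colnames(values)
    if (is.null(region_ids)) region_ids <- default_region_ids(N)
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != N || anyDuplicated(region_ids))
    stop("region_ids must be unique and match the number of columns",
         call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column '%s'",
                 bad[1], region_ids[bad[2]]), call. = FALSE)
  }
  if (check_variance) {
    sds <- apply(values, 2, stats::sd)
    if (any(sds == 0))
      stop(sprintf("constant (zero-variance) column(s): %s",
                   paste(region_ids[sds == 0], collapse = ", ")), call. = FALSE)
  }
  colnames(values) <- region_ids
  rownames(values) <- NULL
  structure(values, subject_id = subject_id, class = c("timecourse_matrix", "matrix"))
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat(sprintf("timecourse_matrix '%s': L=%d time points x N=%d regions\n",
              attr(x, "subject_id"), nrow(x), ncol(x)))
  invisible(x)
}

# delimiter by extension: .csv -> comma, anything else -> tab
infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Load a regional time-course matrix from delimited text
#'
#' Reads a TSV or CSV (delimiter chosen by extension) whose rows are time
#' points and columns are regions.  A single header row of region labels is
#' detected automatically; without one, labels `r001...rNNN` are generated.
#'
#' @param path path to the delimited text file.
#' @param subject_id subject identifier to attach.
#' @return A [timecourse_matrix()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(matrix(rnorm(30), 10, 3), tf, sep = "\t",
#'             row.names = FALSE, col.names = FALSE)
#' tc <- load_timecourses(tf, "s01")
#' dim(tc)
#' @export
load_timecourses <- function(path, subject_id = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- infer_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  raw <- utils::read.table(path, sep = sep, header = has_header,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  vals <- suppressWarnings(apply(as.matrix(raw), c(1, 2), as.numeric))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at row %d, column %d of %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  ids <- if (has_header) colnames(raw) else NULL
  timecourse_matrix(unname(vals), region_ids = ids, subject_id = subject_id)
}

#' Save a binary network to disk
#'
#' @param net a [binary_network()].
#' @param path output file path.
#' @param format `"dense"` writes an N x N 0/1 TSV with region labels as
#'   header row and first column; `"edgelist"` writes each undirected edge
#'   once (endpoints in region order, rows lexicographic) preceded by a
#'   `# regions:` comment line that preserves the full region ordering so
#'   isolated regions survive a round trip.
#' @return `path`, invisibly.  `load_network(save_network(net, p, f), f)`
#'   reproduces `net` exactly in both formats.
#' @seealso [load_network()]
#' @export
save_network <- function(net, path, format = c("dense", "edgelist")) {
  stopifnot(inherits(net, "binary_network"))
  format <- match.arg(format)
  if (format == "dense") {
    m <- net$adjacency
    storage.mode(m) <- "integer"
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else {
    edges <- network_edges(net)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# regions: ", paste(net$region_ids, collapse = ",")), con)
    writeLines("from\tto", con)
    if (nrow(edges) > 0)
      writeLines(paste(edges[, 1], edges[, 2], sep = "\t"), con)
  }
  invisible(path)
}

#' Load a binary network written by [save_network()]
#'
#' @param path file path.
#' @param format `"dense"` or `"edgelist"`.
#' @return A [binary_network()].
#' @export
load_network <- function(path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    binary_network(m, region_ids = rownames(m))
  } else {
    lines <- readLines(path)
    if (!grepl("^# regions: ", lines[1]))
      stop("edge-list file missing '# regions:' header line", call. = FALSE)
    ids <- strsplit(sub("^# regions: ", "", lines[1]), ",", fixed = TRUE)[[1]]
    n <- length(ids)
    adj <- matrix(0, n, n, dimnames = list(ids, ids))
    body <- lines[-(1:2)]
    body <- body[nzchar(body)]
    for (ln in body) {
      pr <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (!all(pr %in% ids))
        stop(sprintf("edge endpoint not in region list: %s", ln), call. = FALSE)
      adj[pr[1], pr[2]] <- adj[pr[2], pr[1]] <- 1
    }
    binary_network(adj, region_ids = ids)
  }
}

#' Load a region table with centroid coordinates
#'
#' @param path CSV with columns `region_id,name,hemisphere,x,y,z`;
#'   coordinates in millimetres, `hemisphere` one of `left,right,none`.
#' @return A data frame of class `region_table`.
#' @export
load_region_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  region_table(df)
}

#' @rdname load_region_table
#' @param df data frame with the columns listed above.
#' @export
region_table <- function(df) {
  need <- c("region_id", "name", "hemisphere", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("region table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df$region_id <- as.character(df$region_id)
  if (anyDuplicated(df$region_id))
    stop("region_id values must be unique", call. = FALSE)
  if (!all(df$hemisphere %in% c("left", "right", "none")))
    stop("hemisphere must be one of left, right, none", call. = FALSE)
  if (anyNA(df[, c("x", "y", "z")]))
    stop("centroid coordinates must not contain missing values", call. = FALSE)
  class(df) <- c("region_table", "data.frame")
  df
}

#' Assemble a two-group cohort of subjects
#'
#' @param timecourses list of [timecourse_matrix()] objects.
#' @param groups character vector of group labels (`"A"`/`"B"`), one per
#'   subject.
#' @param metadata free-form named list.
#' @return A `cohort` object: list with `subjects` (each a list `tc`,
#'   `group`, `subject_id`) and `metadata`.
#' @export
cohort <- function(timecourses, groups, metadata = list()) {
  groups <- as.character(groups)
  if (length(timecourses) != length(groups))
    stop("one group label per subject required", call. = FALSE)
  if (length(unique(groups)) != 2)
    stop("exactly two groups required", call. = FALSE)
  subjects <- Map(function(tc, g) {
    stopifnot(inherits(tc, "timecourse_matrix"))
    list(tc = tc, group = g, subject_id = attr(tc, "subject_id"))
  }, timecourses, groups)
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  names(subjects) <- ids
  structure(list(subjects = subjects, metadata = metadata), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  g <- cohort_groups(x)
  cat(sprintf("cohort: %d subjects (%s)\n", length(x$subjects),
              paste(sprintf("%s=%d", names(table(g)), table(g)), collapse = ", ")))
  invisible(x)
}

#' Group label of every subject in a cohort
#' @param ch a [cohort()].
#' @return Named character vector of group labels, in subject order.
#' @export
cohort_groups <- function(ch) {
  vapply(ch$subjects, `[[`, "", "group")
}

#' Load a cohort from a manifest file
#'
#' @param manifest_path CSV with columns `subject_id,group,path`; `path` is
#'   resolved relative to the manifest's directory unless absolute.
#' @return A [cohort()].
#' @export
load_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(man)))
    stop("manifest needs columns subject_id, group, path", call. = FALSE)
  base <- dirname(manifest_path)
  tcs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    load_timecourses(p, subject_id = man$subject_id[i])
  })
  cohort(tcs, man$group)
}
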