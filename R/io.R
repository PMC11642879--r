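## I/O for cell_population: h5ad (HDF5 annotated-matrix format, interoperable
## with the Python anndata ecosystem) and a plain-text delimited bundle.

## ---- small rhdf5 helpers ---------------------------------------------------

## rhdf5 presents dims in R (column-major) order while h5py readers see them
## reversed; matrices are therefore written transposed so that an anndata
## reader sees cells x features.
.h5_write_attr <- function(file, path, name, value) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  obj <- if (path == "/") rhdf5::H5Gopen(fid, "/") else rhdf5::H5Oopen(fid, path)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, obj, name,
                          asScalar = is.character(value) && length(value) == 1L)
  invisible(NULL)
}

.h5_encoding <- function(file, path, type, version) {
  .h5_write_attr(file, path, "encoding-type", type)
  .h5_write_attr(file, path, "encoding-version", version)
}

.h5_write_array <- function(file, path, x) {
  if (is.matrix(x)) {
    rhdf5::h5write(t(unname(x)), file, path)
    .h5_encoding(file, path, "array", "0.2.0")
  } else if (is.character(x)) {
    rhdf5::h5write(x, file, path)
    .h5_encoding(file, path, "string-array", "0.2.0")
  } else if (is.logical(x)) {
    rhdf5::h5write(as.integer(x), file, path)
    .h5_encoding(file, path, "array", "0.2.0")
    .h5_write_attr(file, path, "graphvelo-dtype", "bool")
  } else {
    rhdf5::h5write(x, file, path)
    .h5_encoding(file, path, "array", "0.2.0")
  }
}

.h5_write_df <- function(file, path, df) {
  rhdf5::h5createGroup(file, path)
  .h5_encoding(file, path, "dataframe", "0.2.0")
  .h5_write_attr(file, path, "_index", "_index")
  cols <- names(df)
  ## zero-length string attributes are not portable; always store something
  .h5_write_attr(file, path, "column-order",
                 if (length(cols)) cols else "_index")
  idx <- rownames(df)
  if (is.null(idx)) idx <- as.character(seq_len(nrow(df)))
  .h5_write_array(file, paste0(path, "/_index"), idx)
  for (nm in cols) {
    v <- df[[nm]]
    if (is.factor(v)) v <- as.character(v)
    .h5_write_array(file, paste0(path, "/", nm), v)
  }
}

.h5_read_array <- function(file, path) {
  x <- rhdf5::h5read(file, path, read.attributes = TRUE)
  at <- attributes(x)
  if (!is.null(at[["graphvelo-dtype"]]) &&
      identical(as.character(at[["graphvelo-dtype"]]), "bool")) {
    dd <- dim(x); x <- as.logical(x); dim(x) <- dd
  }
  enc <- at[["encoding-type"]]
  attributes(x) <- attributes(x)[c("dim")]
  if (is.matrix(x)) x <- t(x)
  if (!is.null(enc) && identical(as.character(enc), "string-array"))
    x <- as.character(x)
  x
}

.h5_read_df <- function(file, path, ls_tab) {
  sub <- ls_tab[ls_tab$group == path, , drop = FALSE]
  idx <- as.character(rhdf5::h5read(file, paste0(path, "/_index")))
  cols <- setdiff(sub$name, "_index")
  df <- data.frame(row.names = idx)
  for (nm in cols) {
    cpath <- paste0(path, "/", nm)
    if (sub$otype[match(nm, sub$name)] == "H5I_GROUP") {
      ## anndata categorical: codes (0-based) + categories
      codes <- as.integer(rhdf5::h5read(file, paste0(cpath, "/codes")))
      cats <- as.character(rhdf5::h5read(file, paste0(cpath, "/categories")))
      v <- ifelse(codes < 0L, NA_character_, cats[codes + 1L])
    } else {
      v <- .h5_read_array(file, cpath)
    }
    df[[nm]] <- as.vector(v)
  }
  df
}

.h5_write_csr_graph <- function(file, g) {
  rhdf5::h5createGroup(file, "obsp")
  .h5_encoding(file, "obsp", "dict", "0.1.0")
  rhdf5::h5createGroup(file, "obsp/distances")
  n <- g$n_cells
  counts <- lengths(g$indices)
  ## within-row CSR entries sorted by column index for canonical form
  data <- numeric(sum(counts)); cols <- integer(sum(counts))
  pos <- 1L
  for (i in seq_len(n)) {
    o <- order(g$indices[[i]])
    m <- counts[i]
    if (m) {
      cols[pos:(pos + m - 1L)] <- g$indices[[i]][o] - 1L
      data[pos:(pos + m - 1L)] <- g$distances[[i]][o]
      pos <- pos + m
    }
  }
  rhdf5::h5write(data, file, "obsp/distances/data")
  rhdf5::h5write(cols, file, "obsp/distances/indices")
  rhdf5::h5write(as.integer(c(0L, cumsum(counts))), file,
                 "obsp/distances/indptr")
  .h5_encoding(file, "obsp/distances", "csr_matrix", "0.1.0")
  .h5_write_attr(file, "obsp/distances", "shape", as.integer(c(n, n)))
}

.h5_read_csr_graph <- function(file, path, n, source) {
  data <- as.numeric(rhdf5::h5read(file, paste0(path, "/data")))
  cols <- as.integer(rhdf5::h5read(file, paste0(path, "/indices")))
  indptr <- as.integer(rhdf5::h5read(file, paste0(path, "/indptr")))
  idx <- vector("list", n); dst <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- if (indptr[i + 1L] > indptr[i]) (indptr[i] + 1L):indptr[i + 1L]
           else integer(0)
    ii <- cols[sel] + 1L; dd <- data[sel]
    o <- order(dd, ii)
    idx[[i]] <- ii[o]; dst[[i]] <- dd[o]
  }
  neighbor_graph(idx, dst, n, source = source)
}

.h5_read_sparse_dense <- function(file, path, ls_tab, n, f) {
  row <- ls_tab[ls_tab$group == dirname2(path) & ls_tab$name == basename(path),
                , drop = FALSE]
  if (nrow(row) && row$otype == "H5I_GROUP") {
    at <- rhdf5::h5readAttributes(file, path)
    enc <- as.character(at[["encoding-type"]])
    data <- as.numeric(rhdf5::h5read(file, paste0(path, "/data")))
    indices <- as.integer(rhdf5::h5read(file, paste0(path, "/indices")))
    indptr <- as.integer(rhdf5::h5read(file, paste0(path, "/indptr")))
    M <- matrix(0, n, f)
    if (identical(enc, "csr_matrix")) {
      for (i in seq_len(n)) {
        sel <- if (indptr[i + 1L] > indptr[i]) (indptr[i] + 1L):indptr[i + 1L]
               else integer(0)
        M[i, indices[sel] + 1L] <- data[sel]
      }
    } else if (identical(enc, "csc_matrix")) {
      for (j in seq_len(f)) {
        sel <- if (indptr[j + 1L] > indptr[j]) (indptr[j] + 1L):indptr[j + 1L]
               else integer(0)
        M[indices[sel] + 1L, j] <- data[sel]
      }
    } else stop("unsupported sparse encoding '", enc, "' at ", path,
                call. = FALSE)
    M
  } else {
    .h5_read_array(file, path)
  }
}

dirname2 <- function(p) {
  d <- dirname(p)
  if (d == ".") "/" else if (!startsWith(d, "/")) paste0("/", d) else d
}

## ---- h5ad ------------------------------------------------------------------

.save_h5ad <- function(pop, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  .h5_encoding(path, "/", "anndata", "0.1.0")
  .h5_write_array(path, "X", pop$X)
  rhdf5::h5createGroup(path, "layers")
  .h5_encoding(path, "layers", "dict", "0.1.0")
  for (nm in names(pop$layers))
    .h5_write_array(path, paste0("layers/", nm), pop$layers[[nm]])
  .h5_write_df(path, "obs", pop$obs)
  .h5_write_df(path, "var", pop$var)
  rhdf5::h5createGroup(path, "obsm")
  .h5_encoding(path, "obsm", "dict", "0.1.0")
  for (nm in names(pop$obsm))
    .h5_write_array(path, paste0("obsm/", nm), pop$obsm[[nm]])
  rhdf5::h5createGroup(path, "uns")
  .h5_encoding(path, "uns", "dict", "0.1.0")
  if (!is.null(pop$graph)) {
    .h5_write_csr_graph(path, pop$graph)
    .h5_write_array(path, "uns/graph_source", pop$graph$source)
  }
  invisible(path)
}

.load_h5ad <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls_tab <- rhdf5::h5ls(path)
  obs <- if (any(ls_tab$group == "/obs"))
    .h5_read_df(path, "/obs", ls_tab) else NULL
  var <- if (any(ls_tab$group == "/var"))
    .h5_read_df(path, "/var", ls_tab) else NULL
  n <- if (!is.null(obs)) nrow(obs) else NA_integer_
  f <- if (!is.null(var)) nrow(var) else NA_integer_
  X <- .h5_read_sparse_dense(path, "/X", ls_tab, n, f)
  if (!is.null(obs)) rownames(X) <- rownames(obs)
  if (!is.null(var)) colnames(X) <- rownames(var)
  layers <- list()
  lay_names <- ls_tab$name[ls_tab$group == "/layers"]
  for (nm in lay_names) {
    L <- .h5_read_sparse_dense(path, paste0("/layers/", nm), ls_tab,
                               nrow(X), ncol(X))
    dimnames(L) <- dimnames(X)
    layers[[nm]] <- L
  }
  obsm <- list()
  for (nm in ls_tab$name[ls_tab$group == "/obsm"])
    obsm[[nm]] <- .h5_read_array(path, paste0("/obsm/", nm))
  graph <- NULL
  if (any(ls_tab$group == "/obsp" & ls_tab$name == "distances")) {
    src <- "external-wnn"
    if (any(ls_tab$group == "/uns" & ls_tab$name == "graph_source"))
      src <- as.character(rhdf5::h5read(path, "uns/graph_source"))
    graph <- .h5_read_csr_graph(path, "/obsp/distances", nrow(X), src)
  }
  cell_population(X, layers = layers, obs = obs, var = var, obsm = obsm,
                  graph = graph)
}

## ---- delimited bundle ------------------------------------------------------

.fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ifelse(is.nan(x[is.na(x)]), "NaN", "NA")
  out
}

.write_num_csv <- function(m, path) {
  df <- as.data.frame(matrix(.fmt_double(unname(m)), nrow(m), ncol(m)),
                      stringsAsFactors = FALSE)
  colnames(df) <- colnames(m)
  df <- cbind(data.frame(.row = rownames(m), stringsAsFactors = FALSE), df)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
}

.read_num_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1]]
  df <- df[, -1, drop = FALSE]
  ## column-wise conversion: as.matrix() on a mixed-type data.frame would
  ## route numbers through format() and lose precision
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(rn, colnames(df)))
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (is.character(col)) col[col %in% c("NA", "NaN")] <- NA
    m[, j] <- as.numeric(col)
  }
  m
}

.save_delimited <- function(pop, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  .write_num_csv(pop$X, file.path(path, "X.csv"))
  for (nm in names(pop$layers))
    .write_num_csv(pop$layers[[nm]], file.path(path, paste0("layer_", nm, ".csv")))
  write.csv(cbind(data.frame(.row = rownames(pop$obs)), pop$obs),
            file.path(path, "obs.csv"), row.names = FALSE)
  write.csv(cbind(data.frame(.row = rownames(pop$var)), pop$var),
            file.path(path, "var.csv"), row.names = FALSE)
  for (nm in names(pop$obsm))
    .write_num_csv(pop$obsm[[nm]], file.path(path, paste0("obsm_", nm, ".csv")))
  if (!is.null(pop$graph)) {
    g <- pop$graph
    df <- data.frame(
      cell = rep.int(seq_len(g$n_cells), lengths(g$indices)),
      neighbor = unlist(g$indices, use.names = FALSE),
      distance = .fmt_double(unlist(g$distances, use.names = FALSE)))
    write.csv(df, file.path(path, "graph.csv"), row.names = FALSE)
    write.csv(data.frame(key = "graph_source", value = g$source),
              file.path(path, "meta.csv"), row.names = FALSE)
  }
  invisible(path)
}

.load_delimited <- function(path) {
  xf <- file.path(path, "X.csv")
  if (!file.exists(xf)) stop("no X.csv in bundle ", path, call. = FALSE)
  X <- .read_num_csv(xf)
  layers <- list()
  for (fp in list.files(path, pattern = "^layer_.*\\.csv$", full.names = TRUE)) {
    nm <- sub("^layer_(.*)\\.csv$", "\\1", basename(fp))
    layers[[nm]] <- .read_num_csv(fp)
  }
  read_df <- function(fp, nr) {
    if (!file.exists(fp)) return(NULL)
    df <- read.csv(fp, check.names = FALSE, stringsAsFactors = FALSE)
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    rownames(df) <- rn
    df
  }
  obs <- read_df(file.path(path, "obs.csv"))
  var <- read_df(file.path(path, "var.csv"))
  obsm <- list()
  for (fp in list.files(path, pattern = "^obsm_.*\\.csv$", full.names = TRUE)) {
    nm <- sub("^obsm_(.*)\\.csv$", "\\1", basename(fp))
    obsm[[nm]] <- .read_num_csv(fp)
  }
  graph <- NULL
  gf <- file.path(path, "graph.csv")
  if (file.exists(gf)) {
    gdf <- read.csv(gf, stringsAsFactors = FALSE)
    src <- "external-wnn"
    mf <- file.path(path, "meta.csv")
    if (file.exists(mf)) {
      meta <- read.csv(mf, stringsAsFactors = FALSE)
      if ("graph_source" %in% meta$key)
        src <- meta$value[match("graph_source", meta$key)]
    }
    n <- nrow(X)
    idx <- split(as.integer(gdf$neighbor), factor(gdf$cell, levels = seq_len(n)))
    dst <- split(as.numeric(gdf$distance), factor(gdf$cell, levels = seq_len(n)))
    graph <- neighbor_graph(unname(idx), unname(dst), n, source = src)
  }
  cell_population(X, layers = layers, obs = obs, var = var, obsm = obsm,
                  graph = graph)
}

## ---- public interface ------------------------------------------------------

#' Read a cell population from disk
#'
#' Supports the h5ad annotated-matrix format (dense or CSR/CSC sparse `X`
#' and layers, `obs`/`var` data frames, `obsm` embeddings, `obsp/distances`
#' neighbour graph) and a plain-text delimited bundle (a directory of CSV
#' files: `X.csv`, `layer_<name>.csv`, `obs.csv`, `var.csv`,
#' `obsm_<name>.csv`, `graph.csv`).
#'
#' @param path file (h5ad) or directory (delimited bundle).
#' @param format `"h5ad"` or `"delimited"`; guessed from `path` by default.
#' @return A validated [cell_population()].
#' @export
load_population <- function(path, format = c("auto", "h5ad", "delimited")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "delimited" else "h5ad"
  if (!file.exists(path) && !dir.exists(path))
    stop("cannot read '", path, "': no such file or directory", call. = FALSE)
  switch(format,
         h5ad = .load_h5ad(path),
         delimited = .load_delimited(path))
}

#' Write a cell population to disk
#'
#' Inverse of [load_population()]: matrices round-trip to numerical
#' precision and annotations exactly (h5ad stores doubles bit-exactly; the
#' delimited bundle prints 17 significant digits).
#'
#' @param pop a validated `cell_population`.
#' @param path destination file (h5ad) or directory (delimited).
#' @param format `"h5ad"` or `"delimited"`; guessed from `path` by default.
#' @return `path`, invisibly.
#' @export
save_population <- function(pop, path,
                            format = c("auto", "h5ad", "delimited")) {
  format <- match.arg(format)
  validate_population(pop)
  if (format == "auto")
    format <- if (grepl("\\.h5ad$", path)) "h5ad" else "delimited"
  switch(format,
         h5ad = .save_h5ad(pop, path),
         delimited = .save_delimited(pop, path))
  invisible(path)
}
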