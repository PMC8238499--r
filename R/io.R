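# Readers/writers for the standard single-cell exchange formats. Matrix
# parsing goes through Matrix::readMM / utils::read.delim; the optional HDF5
# container (an h5ad-like layout: X, obs, var, obsm, obsp) uses rhdf5 when
# available.

#' Read a 10x-style MTX triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`
#' in `path` (uncompressed or gzipped).
#'
#' @param path directory holding the triplet.
#' @param modality modality tag for the resulting [counts_matrix()].
#' @return a `CountsMatrix` (sparse).
#' @export
read_10x_mtx <- function(path, modality = "rna") {
  pick <- function(cands) {
    for (f in cands) {
      for (ext in c("", ".gz")) {
        fp <- file.path(path, paste0(f, ext))
        if (file.exists(fp)) return(fp)
      }
    }
    stopf("none of %s found in %s", paste(cands, collapse = "/"), path)
  }
  m <- Matrix::readMM(pick("matrix.mtx"))
  feats <- utils::read.delim(pick(c("features.tsv", "genes.tsv")),
                             header = FALSE, stringsAsFactors = FALSE)
  bcs <- utils::read.delim(pick("barcodes.tsv"), header = FALSE,
                           stringsAsFactors = FALSE)
  m <- methods::as(m, "CsparseMatrix")
  counts_matrix(m, feature_ids = feats[[if (ncol(feats) >= 2) 2 else 1]],
                cell_ids = bcs[[1]], modality = modality)
}

#' Read a dense features x cells CSV/TSV matrix
#'
#' First column = feature ids, header row = cell ids.
#'
#' @param file path to the delimited file.
#' @param sep field separator (guessed from the extension by default).
#' @param modality modality tag.
#' @return a `CountsMatrix` (dense).
#' @export
read_dense_matrix <- function(file, sep = NULL, modality = "rna") {
  if (is.null(sep))
    sep <- if (grepl("\\.csv(\\.gz)?$", file)) "," else "\t"
  df <- utils::read.delim(file, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE)
  counts_matrix(as.matrix(df), modality = modality)
}

#' Write a multimodal analysis to an HDF5 container
#'
#' Stores each modality's counts (CSC triplets), cell metadata, embeddings
#' (`obsm`), and graphs (`obsp`, as sparse triplets) in an h5ad-like layout.
#' Requires the `rhdf5` package.
#'
#' @param path output `.h5` file (overwritten).
#' @param modalities named list of `CountsMatrix` / matrices.
#' @param cell_meta optional data frame of per-cell metadata.
#' @param embeddings optional named list of cells x d matrices.
#' @param graphs optional named list of sparse matrices or `NeighborGraph`s.
#' @return invisibly, the path.
#' @export
write_h5_container <- function(path, modalities, cell_meta = NULL,
                               embeddings = NULL, graphs = NULL) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("write_h5_container requires the 'rhdf5' package")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  write_sparse <- function(group, m) {
    m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    rhdf5::h5createGroup(path, group)
    rhdf5::h5write(m@x, path, paste0(group, "/data"))
    rhdf5::h5write(m@i, path, paste0(group, "/indices"))
    rhdf5::h5write(m@p, path, paste0(group, "/indptr"))
    rhdf5::h5write(dim(m), path, paste0(group, "/shape"))
  }
  rhdf5::h5createGroup(path, "modalities")
  for (nm in names(modalities)) {
    cm <- modalities[[nm]]
    vals <- as_feature_matrix(cm)
    grp <- paste0("modalities/", nm)
    write_sparse(grp, vals)
    rhdf5::h5write(rownames(vals) %||% character(0), path, paste0(grp, "/features"))
    rhdf5::h5write(colnames(vals) %||% character(0), path, paste0(grp, "/cells"))
  }
  if (!is.null(cell_meta)) {
    rhdf5::h5write(as.data.frame(cell_meta), path, "obs")
  }
  if (!is.null(embeddings)) {
    rhdf5::h5createGroup(path, "obsm")
    for (nm in names(embeddings))
      rhdf5::h5write(as.matrix(embeddings[[nm]]), path, paste0("obsm/", nm))
  }
  if (!is.null(graphs)) {
    rhdf5::h5createGroup(path, "obsp")
    for (nm in names(graphs)) {
      g <- graphs[[nm]]
      m <- if (inherits(g, "NeighborGraph") && !inherits(g, "WnnGraph")) {
        n <- nrow(g$indices)
        Matrix::sparseMatrix(i = rep(seq_len(n), ncol(g$indices)),
                             j = as.vector(g$indices),
                             x = as.vector(g$distances), dims = c(n, n))
      } else if (inherits(g, "WnnGraph")) {
        n <- nrow(g$indices)
        Matrix::sparseMatrix(i = rep(seq_len(n), ncol(g$indices)),
                             j = as.vector(g$indices),
                             x = as.vector(g$similarities), dims = c(n, n))
      } else g
      write_sparse(paste0("obsp/", nm), m)
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a container written by [write_h5_container()]
#'
#' @param path the `.h5` file.
#' @return list with `modalities` (sparse matrices with dimnames),
#'   `cell_meta`, `embeddings`, `graphs` (those present).
#' @export
read_h5_container <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("read_h5_container requires the 'rhdf5' package")
  ls <- rhdf5::h5ls(path)
  read_sparse <- function(group) {
    shape <- rhdf5::h5read(path, paste0(group, "/shape"))
    Matrix::sparseMatrix(i = as.integer(rhdf5::h5read(path, paste0(group, "/indices"))) + 1L,
                         p = as.integer(rhdf5::h5read(path, paste0(group, "/indptr"))),
                         x = as.numeric(rhdf5::h5read(path, paste0(group, "/data"))),
                         dims = as.integer(shape))
  }
  groups_in <- function(parent)
    ls$name[ls$group == paste0("/", parent) & ls$otype == "H5I_GROUP"]
  out <- list()
  out$modalities <- lapply(stats::setNames(nm = groups_in("modalities")), function(nm) {
    grp <- paste0("modalities/", nm)
    m <- read_sparse(grp)
    feats <- as.character(rhdf5::h5read(path, paste0(grp, "/features")))
    cells <- as.character(rhdf5::h5read(path, paste0(grp, "/cells")))
    if (length(feats) == nrow(m)) rownames(m) <- feats
    if (length(cells) == ncol(m)) colnames(m) <- cells
    m
  })
  if ("obs" %in% ls$name[ls$group == "/"])
    out$cell_meta <- rhdf5::h5read(path, "obs")
  if (any(ls$group == "/obsm"))
    out$embeddings <- lapply(stats::setNames(nm = ls$name[ls$group == "/obsm"]),
                             function(nm) rhdf5::h5read(path, paste0("obsm/", nm)))
  if (any(ls$group == "/obsp"))
    out$graphs <- lapply(stats::setNames(nm = groups_in("obsp")),
                         function(nm) read_sparse(paste0("obsp/", nm)))
  rhdf5::h5closeAll()
  out
}
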