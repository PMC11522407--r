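#' Read and write labelled numeric matrices
#'
#' The canonical dense format is tab-separated text with a header row of
#' column labels and row labels in the first column. Sparse matrices are
#' supported through matrix-market files (`.mtx`), with row and column
#' labels in sibling files `<stem>.rows.txt` and `<stem>.cols.txt` (one
#' label per line).
#'
#' @param m numeric matrix with dimnames.
#' @param path output/input file; a `.mtx` extension selects the sparse
#'   format.
#' @return `read_count_matrix()` returns a dense labelled matrix;
#'   `write_count_matrix()` returns `path` invisibly.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_count_matrix <- function(m, path) {
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(as.numeric(m), nrow(m), ncol(m),
                                   sparse = TRUE), path)
    writeLines(rownames(m), paste0(stem, ".rows.txt"))
    writeLines(colnames(m), paste0(stem, ".cols.txt"))
  } else {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(paste0(stem, ".rows.txt"))
    colnames(m) <- readLines(paste0(stem, ".cols.txt"))
    return(m)
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Load a spot dataset from files
#'
#' Reads the alternated-read matrix, total-read matrix, spot coordinates
#' and per-spot cell counts, reconciles mutation and spot label order of
#' `A` against `D` by label (not by position), and validates all
#' invariants before returning.
#'
#' @param a_path,d_path count matrices (TSV or `.mtx`), mutations x spots.
#' @param coords_path TSV with columns `spot`, `x`, `y`.
#' @param cells_path TSV with columns `spot`, `n_cells`.
#' @return A validated [spot_dataset()].
#' @export
load_spot_dataset <- function(a_path, d_path, coords_path, cells_path) {
  A <- read_count_matrix(a_path)
  D <- read_count_matrix(d_path)
  miss_r <- setdiff(rownames(D), rownames(A))
  miss_c <- setdiff(colnames(D), colnames(A))
  if (length(miss_r) || length(miss_c) ||
      nrow(A) != nrow(D) || ncol(A) != ncol(D))
    stop("label mismatch between A and D; missing in A: ",
         paste(c(miss_r, miss_c), collapse = ", "))
  A <- A[rownames(D), colnames(D), drop = FALSE]
  cdf <- read.delim(coords_path, stringsAsFactors = FALSE)
  ndf <- read.delim(cells_path, stringsAsFactors = FALSE)
  if (!all(colnames(D) %in% cdf$spot))
    stop("coordinates missing for spots: ",
         paste(setdiff(colnames(D), cdf$spot), collapse = ", "))
  if (!all(colnames(D) %in% ndf$spot))
    stop("cell counts missing for spots: ",
         paste(setdiff(colnames(D), ndf$spot), collapse = ", "))
  coords <- as.matrix(cdf[match(colnames(D), cdf$spot), c("x", "y")])
  rownames(coords) <- colnames(D)
  n <- ndf$n_cells[match(colnames(D), ndf$spot)]
  spot_dataset(A, D, coords, n)
}

#' Write a spot dataset to a directory
#'
#' @param data a [spot_dataset()].
#' @param dir output directory (created if needed).
#' @param sparse write the count matrices as matrix-market files.
#' @return The directory path, invisibly.
#' @export
write_spot_dataset <- function(data, dir, sparse = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (sparse) ".mtx" else ".tsv"
  write_count_matrix(data$A, file.path(dir, paste0("A", ext)))
  write_count_matrix(data$D, file.path(dir, paste0("D", ext)))
  write.table(data.frame(spot = colnames(data$D),
                         x = data$coords[, 1], y = data$coords[, 2]),
              file.path(dir, "coords.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(spot = colnames(data$D), n_cells = data$n_prior),
              file.path(dir, "n_cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Write a simulated dataset (inputs, truth and manifest)
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory.
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_spot_dataset(sim$data, dir)
  write_count_matrix(sim$clones$C, file.path(dir, "C.tsv"))
  write.table(data.frame(clone = colnames(sim$clones$C), F = sim$clones$F),
              file.path(dir, "F.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  Ht <- sim$truth$H_true
  dimnames(Ht) <- list(colnames(sim$data$D), colnames(sim$clones$C))
  write_count_matrix(Ht, file.path(tdir, "H_true.tsv"))
  write.table(data.frame(spot = colnames(sim$data$D), N = sim$truth$N_true),
              file.path(tdir, "N_true.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- sim$setup
  class(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Write posterior results
#'
#' Emits the clone-proportion table (spots x clones), the refined
#' cell-count table, the per-variant expression table, an acceptance-rate
#' report and a JSON manifest echoing the chain settings for provenance.
#'
#' @param fit a `posterior_summary` from [run_chain()].
#' @param dir output directory.
#' @return The directory path, invisibly.
#' @export
write_posterior_summary <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  H <- fit$H_mean
  if (is.null(rownames(H))) rownames(H) <- paste0("spot", seq_len(nrow(H)))
  if (is.null(colnames(H))) colnames(H) <- paste0("clone", seq_len(ncol(H)))
  write_count_matrix(H, file.path(dir, "clone_proportions.tsv"))
  write.table(data.frame(spot = rownames(H), n_cells = fit$N_mean),
              file.path(dir, "cell_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_count_matrix(fit$Phi_mean, file.path(dir, "phi.tsv"))
  rep <- c(sprintf("kept_samples\t%d", fit$kept),
           sprintf("accept_phi\t%.4f", fit$accept_rates[["phi"]]),
           sprintf("accept_g\t%.4f", fit$accept_rates[["g"]]),
           sprintf("accept_n\t%.4f", fit$accept_rates[["n"]]))
  writeLines(rep, file.path(dir, "acceptance.tsv"))
  st <- fit$settings
  st$seed <- st$seed %||% NA
  class(st) <- NULL
  jsonlite::write_json(st, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Run a pipeline step from a configuration list
#'
#' Thin programmatic dispatcher behind the command-line interface. The
#' supported steps are `simulate` (write a synthetic dataset),
#' `estimate-hyperparams` (data-driven hyperparameters as JSON), `fit`
#' (run the sampler and write results), `evaluate` (MAE and major-clone
#' accuracy of a fit against simulated truth) and `express`
#' (clone-expression deconvolution).
#'
#' @param step one of the step names above.
#' @param config named list of step arguments; see the CLI script in
#'   `inst/scripts/spotclone` for the accepted keys.
#' @return Step-dependent result, invisibly where the step's product is
#'   its files on disk.
#' @export
run_pipeline <- function(step = c("simulate", "estimate-hyperparams", "fit",
                                  "evaluate", "express"),
                         config = list()) {
  step <- match.arg(step)
  if (!is.null(config$seed)) set.seed(config$seed)
  switch(step,
    "simulate" = {
      setup <- do.call(simulation_setup,
                       config[intersect(names(config),
                                        names(formals(simulation_setup)))])
      sim <- simulate_dataset(setup)
      write_simulation(sim, config$out_dir)
      invisible(sim)
    },
    "estimate-hyperparams" = {
      data <- load_spot_dataset(config$a, config$d, config$coords,
                                config$cells)
      hy <- build_hyperparams(data$n_prior, data$D, config$expected_clones,
                              config$K)
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(unclass(hy),
                           file.path(config$out_dir, "hyperparams.json"),
                           auto_unbox = TRUE, digits = NA)
      invisible(hy)
    },
    "fit" = {
      data <- load_spot_dataset(config$a, config$d, config$coords,
                                config$cells)
      C <- read_count_matrix(config$genotypes)
      fdf <- read.delim(config$frequencies, stringsAsFactors = FALSE)
      clones <- clone_set(C, fdf$F[match(colnames(C), fdf$clone)])
      hyper <- config$hyper %||%
        build_hyperparams(data$n_prior, data$D, config$expected_clones,
                          clones$K, fixed_n = isTRUE(config$fixed_n))
      fit <- run_chain(data, clones, hyper,
                       config$settings %||% chain_settings(seed = config$seed))
      write_posterior_summary(fit, config$out_dir)
      invisible(fit)
    },
    "evaluate" = {
      H_est <- read_count_matrix(config$proportions)
      H_true <- read_count_matrix(config$truth)
      res <- data.frame(
        mae = mean_average_error(H_true, H_est),
        major_clone_accuracy = major_clone_accuracy(H_true, H_est))
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write.table(res, file.path(config$out_dir, "evaluation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res
    },
    "express" = {
      H <- read_count_matrix(config$proportions)
      ndf <- read.delim(config$cells, stringsAsFactors = FALSE)
      Y <- read_count_matrix(config$expression)
      N <- ndf$n_cells[match(rownames(H), ndf$spot)]
      B <- deconvolve_clone_expression(H, pmax(N, 1), Y[rownames(H), ,
                                                        drop = FALSE])
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_count_matrix(B, file.path(config$out_dir,
                                      "clone_expression.tsv"))
      writeLines(rank_genes_by_clone_expression(
        B, min(config$top_n %||% 30, ncol(B))),
        file.path(config$out_dir, "top_genes.txt"))
      invisible(B)
    })
}
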