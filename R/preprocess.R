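# Containers and reversible preprocessing for fused spectral regression.
#
# Scaling parameters are always estimated on training rows and stored in a
# scaling_record; test rows are transformed with the frozen record, never
# refit, so cross-validation stays leak-free.

#' Construct a spectral block
#'
#' One (modality, solvent) measurement block: a samples-by-wavelengths
#' matrix on a common grid.
#'
#' @param name block tag, e.g. `"CD_DCE"`.
#' @param matrix numeric matrix, rows = samples.
#' @param grid `wl_grid` matching `ncol(matrix)`.
#' @param sample_ids character vector matching `nrow(matrix)`.
#' @return list of class `spectral_block`.
#' @export
spectral_block <- function(name, matrix, grid, sample_ids) {
  matrix <- as.matrix(matrix)
  if (!inherits(grid, "wl_grid")) grid <- wl_grid(grid)
  if (ncol(matrix) != length(grid)) {
    stop("block width must equal grid length", call. = FALSE)
  }
  if (nrow(matrix) != length(sample_ids)) {
    stop("row count must equal number of sample_ids", call. = FALSE)
  }
  structure(list(name = name, matrix = matrix, grid = grid,
                 sample_ids = as.character(sample_ids)),
            class = "spectral_block")
}

#' Construct a multiblock dataset
#'
#' @param blocks named list of `spectral_block`s sharing sample ordering.
#' @param Y samples x channels matrix of per-enantiomer concentrations (mM);
#'   channels come in (R, S) pairs per analyte. May be `NULL` for
#'   prediction-only data.
#' @param channel_names column names for `Y`.
#' @param sample_ids common sample ordering.
#' @return list of class `multiblock_dataset`.
#' @export
multiblock_dataset <- function(blocks, Y = NULL, channel_names = colnames(Y),
                               sample_ids = blocks[[1]]$sample_ids) {
  if (length(blocks) == 0L) stop("need at least one block", call. = FALSE)
  for (b in blocks) {
    if (!identical(b$sample_ids, as.character(sample_ids))) {
      stop(sprintf("block '%s' has mismatched sample ids", b$name),
           call. = FALSE)
    }
  }
  if (!is.null(Y)) {
    Y <- as.matrix(Y)
    if (nrow(Y) != length(sample_ids)) {
      stop("Y row count must match sample ids", call. = FALSE)
    }
    colnames(Y) <- channel_names
  }
  structure(list(blocks = blocks, Y = Y, channel_names = channel_names,
                 sample_ids = as.character(sample_ids)),
            class = "multiblock_dataset")
}

#' @export
print.multiblock_dataset <- function(x, ...) {
  cat(sprintf("<multiblock_dataset> %d samples, %d block(s): %s; %s\n",
              length(x$sample_ids), length(x$blocks),
              paste(names(x$blocks), collapse = ", "),
              if (is.null(x$Y)) "no Y" else
                sprintf("Y %d x %d", nrow(x$Y), ncol(x$Y))))
  invisible(x)
}

#' Row-subset a multiblock dataset
#'
#' @param dataset `multiblock_dataset`.
#' @param idx logical or integer row index.
#' @return `multiblock_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  ids <- dataset$sample_ids[idx]
  blocks <- lapply(dataset$blocks, function(b) {
    spectral_block(b$name, b$matrix[idx, , drop = FALSE], b$grid, ids)
  })
  Y <- if (is.null(dataset$Y)) NULL else dataset$Y[idx, , drop = FALSE]
  ds <- multiblock_dataset(blocks, Y, dataset$channel_names, ids)
  roles <- attr(dataset, "roles")
  if (!is.null(roles)) attr(ds, "roles") <- roles[idx]
  ds
}

# Scaling records --------------------------------------------------------

scaling_record <- function(method, means, scales, block_divisor = 1) {
  structure(list(method = method, means = means, scales = scales,
                 block_divisor = block_divisor),
            class = "scaling_record")
}

#' Mean-center a spectral block
#'
#' @param block `spectral_block` with >= 2 samples.
#' @return list `(block, record)`; the record stores the column means.
#' @export
mean_center <- function(block) {
  stopifnot(inherits(block, "spectral_block"))
  if (nrow(block$matrix) < 2L) {
    stop("mean centering needs at least 2 samples", call. = FALSE)
  }
  mu <- colMeans(block$matrix)
  M <- sweep(block$matrix, 2L, mu)
  list(block = spectral_block(block$name, M, block$grid, block$sample_ids),
       record = scaling_record("center_only", mu, rep(1, length(mu))))
}

#' Unit-variance (auto) scale a centered block
#'
#' Divides each column by its sample standard deviation (ddof = 1).
#' Zero-variance columns are passed through with divisor 1 and a warning,
#' keeping wavelength indexing stable.
#'
#' @param block centered `spectral_block`.
#' @param record the centering `scaling_record` to extend (optional).
#' @return list `(block, record)` with `record$method == "unit_variance"`.
#' @export
unit_variance_scale <- function(block, record = NULL) {
  stopifnot(inherits(block, "spectral_block"))
  sds <- apply(block$matrix, 2L, stats::sd)
  degenerate <- !is.finite(sds) | sds < .Machine$double.eps^0.5
  if (any(degenerate)) {
    warning(sprintf("%d zero-variance column(s) passed through unscaled",
                    sum(degenerate)), call. = FALSE)
    sds[degenerate] <- 1
  }
  M <- sweep(block$matrix, 2L, sds, `/`)
  means <- if (is.null(record)) rep(0, ncol(M)) else record$means
  list(block = spectral_block(block$name, M, block$grid, block$sample_ids),
       record = scaling_record("unit_variance", means, sds))
}

#' Block-scale a list of preprocessed blocks
#'
#' Divides every variable of block b by a function of its variable count
#' p_b: `hard` uses sqrt(p_b) (each autoscaled block then carries total
#' variance 1 regardless of width), `soft` uses p_b^(1/4), `none` leaves
#' the blocks untouched.
#'
#' @param blocks list of centered (and typically autoscaled)
#'   `spectral_block`s.
#' @param method `"hard"`, `"soft"` or `"none"`.
#' @return list `(blocks, divisors)`.
#' @export
block_scale <- function(blocks, method = c("none", "hard", "soft")) {
  method <- match.arg(method)
  if (length(blocks) == 0L) stop("empty block list", call. = FALSE)
  divisors <- vapply(blocks, function(b) {
    p <- ncol(b$matrix)
    switch(method, none = 1, hard = sqrt(p), soft = p^0.25)
  }, 0)
  blocks <- mapply(function(b, d) {
    spectral_block(b$name, b$matrix / d, b$grid, b$sample_ids)
  }, blocks, divisors, SIMPLIFY = FALSE)
  list(blocks = blocks, divisors = divisors)
}

#' Column-concatenate blocks into one fused matrix
#'
#' @param blocks list of `spectral_block`s with identical sample ordering.
#' @return list `(matrix, spans)`; `spans` maps each block name to its
#'   0-based half-open column span `[start, end)`.
#' @export
concatenate_blocks <- function(blocks) {
  if (length(blocks) == 0L) stop("empty block list", call. = FALSE)
  ids <- blocks[[1]]$sample_ids
  for (b in blocks) {
    if (!identical(b$sample_ids, ids)) {
      stop(sprintf("block '%s' sample ids do not align", b$name),
           call. = FALSE)
    }
  }
  mats <- lapply(blocks, `[[`, "matrix")
  widths <- vapply(mats, ncol, 0L)
  ends <- cumsum(widths)
  starts <- c(0L, ends[-length(ends)])
  spans <- mapply(function(s, e) c(start = s, end = e), starts, ends,
                  SIMPLIFY = FALSE)
  names(spans) <- vapply(blocks, `[[`, "", "name")
  list(matrix = do.call(cbind, mats), spans = spans)
}

# Dataset-level preprocessing --------------------------------------------

#' Fit a preprocessing transform on a dataset's blocks
#'
#' `scaling = "center"` mean-centers only; `"uv"` adds unit-variance
#' column scaling; `"hard"`/`"soft"` add multiblock scaling on top of
#' unit-variance scaling.
#'
#' @param dataset `multiblock_dataset` (training rows).
#' @param scaling `"center"`, `"uv"`, `"hard"` or `"soft"`.
#' @return object of class `preprocess_record` holding per-block means,
#'   column divisors and block divisors, plus the fused column spans.
#' @export
preprocess_fit <- function(dataset, scaling = c("uv", "center", "hard", "soft")) {
  scaling <- match.arg(scaling)
  recs <- list()
  blocks <- list()
  for (bn in names(dataset$blocks)) {
    cen <- mean_center(dataset$blocks[[bn]])
    if (scaling == "center") {
      recs[[bn]] <- cen$record
      blocks[[bn]] <- cen$block
    } else {
      uv <- suppressWarnings(unit_variance_scale(cen$block, cen$record))
      recs[[bn]] <- uv$record
      blocks[[bn]] <- uv$block
    }
  }
  bs_method <- switch(scaling, hard = "hard", soft = "soft", "none")
  bs <- block_scale(blocks, bs_method)
  for (i in seq_along(recs)) recs[[i]]$block_divisor <- bs$divisors[[i]]
  cc <- concatenate_blocks(bs$blocks)
  structure(list(scaling = scaling, records = recs, spans = cc$spans),
            class = "preprocess_record")
}

#' Apply a frozen preprocessing transform
#'
#' @param prep `preprocess_record` from [preprocess_fit()].
#' @param dataset `multiblock_dataset` (any rows).
#' @return list `(matrix, blocks, spans)`: fused matrix plus the scaled
#'   per-block matrices.
#' @export
preprocess_apply <- function(prep, dataset) {
  stopifnot(inherits(prep, "preprocess_record"))
  if (!setequal(names(prep$records), names(dataset$blocks))) {
    stop("dataset blocks do not match the preprocessing record", call. = FALSE)
  }
  blocks <- list()
  for (bn in names(prep$records)) {
    r <- prep$records[[bn]]
    b <- dataset$blocks[[bn]]
    M <- sweep(b$matrix, 2L, r$means)
    M <- sweep(M, 2L, r$scales, `/`)
    M <- M / r$block_divisor
    blocks[[bn]] <- spectral_block(bn, M, b$grid, b$sample_ids)
  }
  cc <- concatenate_blocks(blocks)
  list(matrix = cc$matrix, blocks = blocks, spans = cc$spans)
}

#' Invert a preprocessing transform on a fused matrix
#'
#' @param prep `preprocess_record`.
#' @param fused matrix in the scaled fused space.
#' @return list of raw-space per-block matrices.
#' @export
preprocess_invert <- function(prep, fused) {
  out <- list()
  for (bn in names(prep$records)) {
    r <- prep$records[[bn]]
    sp <- prep$spans[[bn]]
    M <- fused[, (sp["start"] + 1L):sp["end"], drop = FALSE]
    M <- M * r$block_divisor
    M <- sweep(M, 2L, r$scales, `*`)
    out[[bn]] <- sweep(M, 2L, r$means, `+`)
  }
  out
}

#' Serialize a preprocessing record to JSON
#'
#' @param prep `preprocess_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_json <- function(prep, path) {
  plain <- list(
    scaling = prep$scaling,
    records = lapply(prep$records, function(r) {
      list(method = r$method, means = unname(r$means),
           scales = unname(r$scales), block_divisor = r$block_divisor)
    }),
    spans = lapply(prep$spans, function(s) list(start = unname(s["start"]),
                                                end = unname(s["end"]))))
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
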