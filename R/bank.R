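#' Fit a bank of per-biomarker emulators
#'
#' Fits one independent [gpe()] per column of the response table `Y`
#' ("one emulator per biomarker"). When validation and/or test splits are
#' supplied, records per-biomarker R-squared and ISE scores for each split.
#'
#' @param X Unit-frame training design.
#' @param Y Training responses: `n x m` matrix or data frame with named
#'   columns, one per biomarker.
#' @param noise_free,restarts,seed,maxit Passed to [fit_gpe()] (the seed is
#'   offset per biomarker so restarts differ across emulators).
#' @param X_val,Y_val,X_test,Y_test Optional held-out splits for scoring.
#' @param provenance Free-text run/wave identifier stored with the bank.
#' @return An object of class `gpe_bank`: fields `biomarker_names`,
#'   `emulators` (named list of [gpe()]), `scores` (data frame), and
#'   `provenance`.
#' @export
fit_bank <- function(X, Y, noise_free = FALSE, restarts = 5L, seed = 1L,
                     maxit = 100L, X_val = NULL, Y_val = NULL,
                     X_test = NULL, Y_test = NULL, provenance = "") {
  Y <- as.data.frame(Y)
  if (is.null(names(Y)) || any(!nzchar(names(Y))))
    stop("Y columns must be named (one per biomarker)", call. = FALSE)
  nm <- names(Y)
  emulators <- vector("list", length(nm))
  names(emulators) <- nm
  scores <- list()
  for (k in seq_along(nm)) {
    ## seed keyed to the biomarker's alphabetical rank, not its column
    ## position, so a column permutation refits identically per name
    seed_k <- seed + 1000L * match(nm[k], sort(nm))
    em <- tryCatch(
      fit_gpe(X, Y[[k]], noise_free = noise_free, restarts = restarts,
              seed = seed_k, maxit = maxit),
      error = function(e)
        stop(sprintf("emulator fit failed for biomarker '%s': %s",
                     nm[k], conditionMessage(e)), call. = FALSE))
    emulators[[k]] <- em
    for (split in c("val", "test")) {
      Xs <- if (split == "val") X_val else X_test
      Ys <- if (split == "val") Y_val else Y_test
      if (is.null(Xs)) next
      Ys <- as.data.frame(Ys)
      pr <- predict(em, Xs)
      scores[[length(scores) + 1L]] <- data.frame(
        biomarker = nm[k], split = split,
        r2 = r2_score(pr$mean, Ys[[nm[k]]]),
        ise = ise_score(pr$mean, sqrt(pr$var), Ys[[nm[k]]]))
    }
  }
  structure(list(
    biomarker_names = nm, emulators = emulators,
    scores = if (length(scores)) do.call(rbind, scores) else NULL,
    provenance = provenance
  ), class = "gpe_bank")
}

#' @export
print.gpe_bank <- function(x, ...) {
  cat(sprintf("<gpe_bank: %d emulators [%s]%s>\n", length(x$emulators),
              paste(x$biomarker_names, collapse = ", "),
              if (nzchar(x$provenance)) paste0(", ", x$provenance) else ""))
  if (!is.null(x$scores)) print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Predict all biomarkers from an emulator bank
#'
#' @param bank A `gpe_bank`.
#' @param X Unit-frame matrix of prediction points.
#' @return List of `n x m` matrices `mean` and `var` (columns in
#'   biomarker order).
#' @export
predict_bank <- function(bank, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  m <- length(bank$emulators)
  mu <- matrix(NA_real_, nrow(X), m, dimnames = list(NULL, bank$biomarker_names))
  va <- mu
  for (k in seq_len(m)) {
    pr <- predict(bank$emulators[[k]], X)
    mu[, k] <- pr$mean
    va[, k] <- pr$var
  }
  list(mean = mu, var = va)
}

#' Persist an emulator bank as JSON + CSV
#'
#' Hyperparameters, biomarker names and provenance go to `<name>.json` at
#' full decimal precision (bit-exact round trip); the shared training
#' design and per-biomarker responses go to `<name>_train.csv`.
#'
#' @param bank A `gpe_bank`.
#' @param dir Output directory (created if needed).
#' @param name File stem (default `"bank"`).
#' @return `write_bank()` returns the JSON path invisibly; `read_bank()`
#'   reconstructs the bank (refactorizing, not refitting).
#' @export
write_bank <- function(bank, dir, name = "bank") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ## hyperparameters as %.17g strings: 17 significant digits round-trip
  ## doubles bit-exactly, which plain JSON numbers do not guarantee
  num17 <- function(x) sprintf("%.17g", x)
  hp <- lapply(bank$emulators, function(e)
    list(beta0 = num17(e$beta0), beta = num17(e$beta),
         lengthscales = num17(e$lengthscales),
         outputscale = num17(e$outputscale),
         noise_var = num17(e$noise_var)))
  meta <- list(biomarker_names = bank$biomarker_names,
               provenance = bank$provenance,
               hyperparameters = hp,
               train_csv = paste0(name, "_train.csv"))
  json_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, json_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  X <- bank$emulators[[1]]$X_train
  Ys <- vapply(bank$emulators, function(e) e$y_train, numeric(nrow(X)))
  colnames(Ys) <- paste0("y.", bank$biomarker_names)
  df <- cbind(as.data.frame(X), as.data.frame(Ys))
  utils::write.csv(format(df, digits = 17, trim = TRUE),
                   file.path(dir, meta$train_csv), row.names = FALSE,
                   quote = FALSE)
  invisible(json_path)
}

#' @rdname write_bank
#' @export
read_bank <- function(dir, name = "bank") {
  json_path <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(json_path))
    stop("emulator bank not found: ", json_path, call. = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, meta$train_csv), check.names = FALSE)
  ycols <- grepl("^y\\.", names(df))
  X <- as.matrix(df[, !ycols, drop = FALSE])
  nm <- meta$biomarker_names
  emulators <- vector("list", length(nm))
  names(emulators) <- nm
  for (k in seq_along(nm)) {
    h <- meta$hyperparameters[[nm[k]]]
    emulators[[k]] <- gpe(X, df[[paste0("y.", nm[k])]],
                          beta0 = as.numeric(h$beta0),
                          beta = as.numeric(unlist(h$beta)),
                          lengthscales = as.numeric(unlist(h$lengthscales)),
                          outputscale = as.numeric(h$outputscale),
                          noise_var = as.numeric(h$noise_var))
  }
  structure(list(biomarker_names = nm, emulators = emulators, scores = NULL,
                 provenance = meta$provenance %||% ""),
            class = "gpe_bank")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
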