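# Plain-text serialization: trajectory summaries to CSV, microstate
# snapshots to a structured JSON archive (one entry per agent class /
# lattice).

#' Save a microstate snapshot to JSON
#'
#' Works for both `wsg_microstate` and `viral_microstate` objects; matrices
#' are stored with their dimensions so [load_microstate_json()] restores an
#' identical object.
#'
#' @param micro a microstate object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_microstate_json <- function(micro, path) {
  enc <- function(x) {
    if (is.matrix(x)) list(.matrix = TRUE, dim = dim(x), data = as.vector(x),
                           colnames = colnames(x))
    else if (is.list(x)) lapply(x, enc)
    else x
  }
  obj <- list(class = class(micro)[1], fields = lapply(unclass(micro), enc))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_microstate_json
#' @export
load_microstate_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      dat <- unlist(x$data)
      if (is.null(dat)) dat <- numeric(0)
      m <- matrix(dat, x$dim[1], x$dim[2])
      if (!is.null(x$colnames) && length(x$colnames)) colnames(m) <- x$colnames
      m
    } else if (is.list(x)) lapply(x, dec) else x
  }
  out <- lapply(obj$fields, dec)
  # integer lattices and counters come back numeric; restore storage mode
  if (obj$class == "wsg_microstate") {
    out$grass_alive <- matrix(as.logical(out$grass_alive),
                              nrow(out$grass_alive), ncol(out$grass_alive))
    storage.mode(out$grass_counter) <- "integer"
  } else if (obj$class == "viral_microstate") {
    storage.mode(out$epithelium) <- "integer"
    storage.mode(out$endothelium) <- "integer"
    storage.mode(out$immune) <- "integer"
    out$apoptosis_by_virus <- as.integer(out$apoptosis_by_virus)
  }
  structure(out, class = obj$class)
}

#' Write a macrostate trajectory to CSV
#'
#' @param df data frame (e.g. the `macro` element of [simulate_wsg()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an assimilation result to CSV
#'
#' One row per time: predictive mean and marginal standard deviation per
#' component, and the surprisal of the true trajectory.
#'
#' @param result an `abmkf_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  df <- data.frame(time = result$times, surprisal = result$surprisal)
  mu <- as.data.frame(result$pred_mean)
  names(mu) <- paste0("mean_", colnames(result$pred_mean))
  sd <- as.data.frame(result$pred_sd)
  names(sd) <- paste0("sd_", colnames(result$pred_sd))
  utils::write.csv(cbind(df, mu, sd), path, row.names = FALSE)
  invisible(path)
}
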