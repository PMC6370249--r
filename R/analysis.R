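#' Per-node, per-subsystem mean absolute flux
#'
#' Averages `|flux|` over the reactions of each subsystem, per node. Empty
#' subsystems (no reactions) cannot occur by construction; subsystems whose
#' reactions are all absent from the profiles are dropped with a message.
#'
#' @param profiles Nodes x reactions flux matrix (reaction ids as column
#'   names) or list of `flux_profile`s.
#' @param model The [community_model()] supplying subsystem labels.
#' @return Nodes x subsystems matrix of nonnegative means.
#' @examples
#' mod <- generate_toy_community(2, seed = 1)
#' pr <- lexicographic_fba(mod)
#' subsystem_flux_summary(rbind(node1 = pr$flux), mod)
#' @export
subsystem_flux_summary <- function(profiles, model) {
  if (is.list(profiles) && !is.matrix(profiles))
    profiles <- do.call(rbind, lapply(profiles, function(p) p$flux))
  X <- abs(as.matrix(profiles))
  subs <- split(model$reactions$id, model$reactions$subsystem)
  subs <- lapply(subs, intersect, colnames(X))
  keep <- lengths(subs) > 0
  if (any(!keep))
    message("dropping subsystems with no profiled reactions: ",
            paste(names(subs)[!keep], collapse = ", "))
  subs <- subs[keep]
  out <- vapply(subs, function(ids)
    rowMeans(X[, ids, drop = FALSE]), numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(rownames(X), names(subs)))
  out
}

#' Correlation of happiness with subsystem fluxes
#'
#' Pearson correlation, across nodes, between the happiness index and each
#' subsystem's mean absolute flux, with ranked top-`k` positive and negative
#' lists. Constant flux columns (or constant happiness) yield an undefined
#' correlation, reported as `NA`. No multiple-testing correction is applied;
#' the ranking is exploratory.
#'
#' @param gamma Per-node happiness indices (length = rows of `table`).
#' @param table A [subsystem_flux_summary()] matrix.
#' @param top_k List length (default 10).
#' @return Object of class `happiness_correlation`: data.frame `correlations`
#'   (subsystem, r) plus `top_positive` / `top_negative` data.frames.
#' @export
happiness_flux_correlation <- function(gamma, table, top_k = 10) {
  if (nrow(table) < 3) stop("need >= 3 nodes", call. = FALSE)
  if (length(gamma) != nrow(table))
    stop("gamma length must match table rows", call. = FALSE)
  r <- suppressWarnings(apply(table, 2, function(col)
    if (stats::sd(col) == 0 || stats::sd(gamma) == 0) NA_real_
    else stats::cor(gamma, col)))
  df <- data.frame(subsystem = colnames(table), r = as.numeric(r),
                   row.names = NULL)
  ord <- df[!is.na(df$r), , drop = FALSE]
  pos <- ord[ord$r > 0, , drop = FALSE]
  pos <- pos[order(-pos$r), , drop = FALSE]
  neg <- ord[ord$r < 0, , drop = FALSE]
  neg <- neg[order(neg$r), , drop = FALSE]
  structure(list(correlations = df,
                 top_positive = utils::head(pos, top_k),
                 top_negative = utils::head(neg, top_k)),
            class = "happiness_correlation")
}

#' @export
print.happiness_correlation <- function(x, ...) {
  cat("Happiness-flux Pearson correlations over",
      nrow(x$correlations), "subsystems\n")
  if (nrow(x$top_positive)) {
    cat("  top positive:\n")
    print(x$top_positive, row.names = FALSE)
  }
  if (nrow(x$top_negative)) {
    cat("  top negative:\n")
    print(x$top_negative, row.names = FALSE)
  }
  invisible(x)
}

#' Write a correlation report CSV
#'
#' Columns: epoch, subsystem, r, rank (positive ranks for positive r in
#' decreasing order, negative ranks for negative r).
#'
#' @param corr A [happiness_flux_correlation()] result.
#' @param epoch Epoch index to stamp rows with.
#' @param path Output file; appends when the file exists.
#' @export
write_correlation_report <- function(corr, epoch, path) {
  df <- corr$correlations
  df <- df[!is.na(df$r), , drop = FALSE]
  df$rank <- NA_integer_
  df$rank[order(-df$r)] <- seq_len(nrow(df))
  out <- data.frame(epoch = epoch, df)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
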