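# Projection of classifier posteriors into the 4-axis Laban effort
# space. Each factor (Space, Flow, Weight, Time) is one axis; indulging
# elements carry positive sign, condensing elements negative. Think and
# do posteriors of the same element pool onto the same axis; the neutral
# class contributes to no axis, so a neutral-only posterior sits at the
# origin.

#' Default class-to-axis map
#'
#' Maps every non-neutral class label to its effort factor and sign
#' (indulging = +1, condensing = -1).
#'
#' @return `data.frame` with columns `class`, `factor`, `sign`.
#' @export
laban_axis_map <- function() {
  ef <- laban_efforts()
  rows <- lapply(seq_len(nrow(ef)), function(i) {
    data.frame(
      class = c(class_label("think", ef$factor[i], ef$condensing[i]),
                class_label("do", ef$factor[i], ef$condensing[i]),
                class_label("think", ef$factor[i], ef$indulging[i]),
                class_label("do", ef$factor[i], ef$indulging[i])),
      factor = ef$factor[i],
      sign = c(-1, -1, 1, 1),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Project class posteriors into 4-D Laban effort space
#'
#' Each row of posteriors maps to the point whose coordinate on factor
#' `f` is the signed posterior mass of the classes on that factor:
#' `sum(sign(element) * P(class))`. Coordinates are linear in the
#' posterior and bounded in \[-1, 1\]. Rows whose largest absolute
#' coordinate falls below `tau` are flagged non-expressive (they sit
#' near the origin, where opposing elements cancel or the mass is on
#' neutral).
#'
#' @param posteriors `n x n_classes` matrix with columns named by class
#'   (rows summing to 1), e.g. from [gmm_posterior()].
#' @param axis_map Class-to-axis map; defaults to [laban_axis_map()].
#' @param tau Non-expressiveness threshold on the max absolute
#'   coordinate (default 0.1).
#' @return `data.frame` with columns `Space`, `Flow`, `Weight`, `Time`
#'   and `expressive` (logical).
#' @export
project_laban <- function(posteriors, axis_map = laban_axis_map(),
                          tau = 0.1) {
  posteriors <- as.matrix(posteriors)
  cls <- colnames(posteriors)
  if (is.null(cls)) {
    stop("usage error: posterior columns must be named by class",
         call. = FALSE)
  }
  if (any(abs(rowSums(posteriors) - 1) > 1e-6)) {
    stop("usage error: posterior rows must sum to 1", call. = FALSE)
  }
  unmapped <- setdiff(cls, c("neutral", axis_map$class))
  if (length(unmapped)) {
    stop("configuration error: class(es) missing from axis map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  factors <- c("Space", "Flow", "Weight", "Time")
  coords <- sapply(factors, function(f) {
    on_axis <- axis_map[axis_map$factor == f, ]
    present <- on_axis$class %in% cls
    if (!any(present)) return(numeric(nrow(posteriors)))
    as.numeric(posteriors[, on_axis$class[present], drop = FALSE] %*%
                 on_axis$sign[present])
  })
  coords <- matrix(coords, ncol = length(factors),
                   dimnames = list(NULL, factors))
  expressive <- apply(abs(coords), 1, max) >= tau
  out <- as.data.frame(coords)
  out$expressive <- expressive
  out
}
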