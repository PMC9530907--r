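#' Response transformations for biclustering
#'
#' The phenotype mean \eqn{\mu_{ij}} is transformed before clustering so that
#' homogeneous cells correspond to homogeneous GEI.  Four kinds are available,
#' all using margins over observed cells only (see [margins()]):
#'
#' 1. `mu_ij - mu` — difference from the overall average (direct response);
#' 2. `mu_ij - mu_i. - mu_.j + mu` — difference from genotype and environment
#'    averages.  Under the model \eqn{\mu_{ij} = \mu + G_i + E_j + GEI_{ij} +
#'    \epsilon_{ij}} on complete data this equals \eqn{GEI_{ij} +
#'    \epsilon_{ij}}, the interaction directly;
#' 3. `mu_ij - mu_i.` — difference from the genotype average;
#' 4. `mu_ij - mu_.j` — difference from the environment average.
#'
#' With missing cells the margins are observed-cell means and the algebraic
#' identity for kind 2 holds only approximately.  The transform is pure: it
#' returns a new table with the same missing mask, leaving the input intact.
#'
#' @param x a [phenotype_table()].
#' @param kind integer in 1..4, the response kind.  Default 2 (the direct GEI
#'   expression).
#' @return A [phenotype_table()] of transformed values with attribute
#'   `response_kind` set to `kind`.
#' @export
#' @examples
#' pt <- phenotype_table(matrix(c(1, 3, 2, 5), 2, 2))
#' gei_response(pt, 2)
gei_response <- function(x, kind = 2L) {
  stopifnot(inherits(x, "phenotype_table"))
  kind <- as.integer(kind)
  if (length(kind) != 1L || is.na(kind) || !kind %in% 1:4) {
    stop("response kind must be one of 1, 2, 3, 4")
  }
  m <- margins(x)
  v <- unclass(x)
  v <- switch(kind,
    v - m$overall,
    v - m$genotype - rep(m$environment, each = nrow(v)) + m$overall,
    v - m$genotype,
    v - rep(m$environment, each = nrow(v))
  )
  out <- phenotype_table(v, rownames(x), colnames(x))
  attr(out, "response_kind") <- kind
  out
}
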