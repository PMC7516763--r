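#' Hald cement data
#'
#' The classical 13-observation cement dataset: the heat evolved in calories
#' per gram of cement (`Y`) as a function of the amounts of four ingredients
#' in the mix — tricalcium aluminate (`X1`), tricalcium silicate (`X2`),
#' tetracalcium alumino-ferrite (`X3`) and dicalcium silicate (`X4`). A
#' standard benchmark for all-subsets regression selection; the regressors
#' are strongly collinear (X1 with X3, X2 with X4). Because cement is a
#' mixture of at least two reacting components, single-variable candidate
#' models are conventionally excluded (`min_size = 2` in [select_model()]).
#'
#' The values are embedded in the package source; the same table ships as
#' `system.file("extdata", "hald.csv", package = "picsel")` for the file-based
#' tools.
#'
#' @return A 13 x 5 data frame with columns `X1`, `X2`, `X3`, `X4`, `Y`.
#' @examples
#' head(hald())
#' @export
hald <- function() {
  data.frame(
    X1 = c(7, 1, 11, 11, 7, 11, 3, 1, 2, 21, 1, 11, 10),
    X2 = c(26, 29, 56, 31, 52, 55, 71, 31, 54, 47, 40, 66, 68),
    X3 = c(6, 15, 8, 8, 6, 9, 17, 22, 18, 4, 23, 9, 8),
    X4 = c(60, 52, 20, 47, 33, 22, 6, 44, 22, 26, 34, 12, 12),
    Y = c(78.5, 74.3, 104.3, 87.6, 95.9, 109.2, 102.7, 72.5, 93.1,
          115.9, 83.8, 113.3, 109.4))
}
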