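#' @importFrom rlang %||% .data
#' @importFrom stats predict
#' @importFrom MASS lda qda
#' @importFrom class knn
#' @importFrom glmnet cv.glmnet
#' @importFrom nnet nnet
#' @importFrom rpart rpart rpart.control
#' @importFrom xgboost xgb.train xgb.DMatrix
NULL
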