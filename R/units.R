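#' Physical constants for 177Lu
#'
#' Physical half-life of 177Lu (6.647 days) expressed in hours, and the
#' corresponding physical decay constant in 1/h. The effective decay
#' constant of any tissue can never fall below `LU177_LAMBDA_H`
#' (equivalently, no effective half-life can exceed `LU177_HALF_LIFE_H`),
#' because biological clearance only adds to physical decay.
#'
#' @format Length-one numeric constants.
#' @export
LU177_HALF_LIFE_H <- 6.647 * 24

#' @rdname LU177_HALF_LIFE_H
#' @export
LU177_LAMBDA_H <- log(2) / (6.647 * 24)

# 1 mCi = 37 MBq exactly
MBQ_PER_MCI <- 37

#' Activity and dose unit conversions
#'
#' Conversions between megabecquerel and millicurie (1 mCi = 37 MBq) and
#' between milligray and gray. Doses are tracked internally in mGy;
#' safety limits and reports use Gy.
#'
#' @param x Numeric vector of values to convert.
#' @return Numeric vector of converted values.
#' @examples
#' mbq_to_mci(7400)   # 200 mCi per 7.4 GBq cycle
#' mbq_to_mci(114.7)  # 3.1 mCi
#' @export
mbq_to_mci <- function(x) x / MBQ_PER_MCI

#' @rdname mbq_to_mci
#' @export
mci_to_mbq <- function(x) x * MBQ_PER_MCI

#' @rdname mbq_to_mci
#' @export
mgy_to_gy <- function(x) x / 1000

#' @rdname mbq_to_mci
#' @export
gy_to_mgy <- function(x) x * 1000
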