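# Vectorized exponential integral E1(x) for x > 0.
#
# The cumulative seeding integral of the Gompertz primary reduces to a
# difference of E1 values, evaluated thousands of times per patient batch
# inside the population fit; this implementation is plain vectorized
# arithmetic so those batches stay cheap. Power series below 1.5,
# bottom-up continued fraction above; both to near machine precision.
# Cross-checked against pracma::expint in the test suite.
e1_exp <- function(x) {
  if (any(x <= 0)) abort("E1 requires positive arguments.")
  out <- numeric(length(x))
  lo <- x < 1.5
  if (any(lo)) {
    xs <- x[lo]
    acc <- xs
    term <- xs
    for (k in 1:34) {
      term <- term * (-xs) * k / ((k + 1)^2)
      acc <- acc + term
    }
    out[lo] <- -0.577215664901532861 - log(xs) + acc
  }
  cf <- function(xs, n) {
    f <- xs + 2 * n + 1
    for (k in n:1) f <- xs + 2 * k - 1 - k^2 / f
    exp(-xs) / f
  }
  mid <- !lo & x < 4
  hi <- x >= 4
  if (any(mid)) out[mid] <- cf(x[mid], 40L)
  if (any(hi)) out[hi] <- cf(x[hi], 15L)
  out
}
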