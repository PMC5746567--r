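# Generated closed-form components of the regularized wall Green's
# function (image system for a stokeslet blob above a plane no-slip wall).
# Derived symbolically from the requirements: exact no-slip on the wall,
# exact incompressibility, convergence to the classical singular image
# solution as epsilon -> 0, and regularity at the source point; verified
# against those properties to machine precision.  All arguments may be
# scalars or conformable arrays: a1 = x1 - X1, a2 = x2 - X2, x3 = field
# height, h = source height, e = regularization length.


.blakelet_k1 <- function(a1, a2, x3, h, e) {
  x0 <- a1^2
  x1 <- e^2
  x2 <- h + x3
  x4 <- a2^2 + x0 + x1 + x2^2
  x5 <- x4^(5.0/2.0)
  x6 <- a1^2
  x7 <- e^2
  x8 <- h - x3
  x9 <- a2^2 + x8^2
  x10 <- (x6 + x7 + x9)^(3.0/2.0)
  x11 <- h^2
  x12 <- 6*x11
  x13 <- h*x2
  x14 <- 2*x4
  x15 <- -6*h*x2 + x12 + x4
  x16 <- 1/(x10*x5)
  x17 <- a1*x5
  x18 <- a1*x10
  list(-x16*(x10*(x0*x15 + x1*x12 - 6*x1*x13 + x1*x4 - x11*x14 + x13*x14 + x4^2) - x5*(2*x6 + 2*x7 + x9)), -x16*(-a2*x17 + a2*x15*x18), x16*(-x17*x8 + x18*(h*x14 - x15*x2)))
}


.blakelet_k3 <- function(a1, a2, x3, h, e) {
  x0 <- e^2
  x1 <- h + x3
  x2 <- x1^2
  x4 <- a1^2 + a2^2 + x0 + x2
  x5 <- x4^(5.0/2.0)
  x6 <- h - x3
  x7 <- x5*x6
  x8 <- 6*h
  x9 <- h^2
  x10 <- 6*x9
  x11 <- 2*x4
  x12 <- h*x11 + x1*x10 - x1*x4 - x2*x8
  x13 <- e^2
  x14 <- x6^2
  x15 <- a1^2 + a2^2
  x16 <- (x13 + x14 + x15)^(3.0/2.0)
  x17 <- x12*x16
  x18 <- 1/(x16*x5)
  list(x18*(-a1*x7 + a1*x17), x18*(-a2*x7 + a2*x17), -x18*(x16*(x0*x1*x8 - x0*x10 + x0*x4 - x1*x12 + x11*x9 + x4^2) - x5*(2*x13 + 2*x14 + x15)))
}


# Full 3x3 kernel for all force directions; force along e2 follows from
# the e1 solution by swapping the two wall-parallel axes.  Returns a list
# b[[(k-1)*3 + j]] of the B[j,k] components.
.blakelet_components <- function(a1, a2, x3, h, e) {
  c1 <- .blakelet_k1(a1, a2, x3, h, e)
  c2s <- .blakelet_k1(a2, a1, x3, h, e)   # swapped axes
  c3 <- .blakelet_k3(a1, a2, x3, h, e)
  list(c1[[1]], c1[[2]], c1[[3]],
       c2s[[2]], c2s[[1]], c2s[[3]],
       c3[[1]], c3[[2]], c3[[3]])
}
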