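#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean earth
#' radius). Vectorized over all arguments.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# symmetrize a nearly-symmetric matrix (guards accumulated asymmetry from
# solve()/crossprod round-off)
symz <- function(S) (S + t(S)) / 2

# row-wise Kronecker product (the tensor-product design construction)
row_kron <- function(A, B) {
  pa <- ncol(A); pb <- ncol(B)
  A[, rep(seq_len(pa), each = pb), drop = FALSE] *
    B[, rep(seq_len(pb), times = pa), drop = FALSE]
}
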