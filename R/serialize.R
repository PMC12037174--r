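# Bit-exact little-endian serialization of built indexes.  Layout: an 8-byte
# magic, int32 version and variant tags, scalar metadata, then each succinct
# sequence with its own type tag so corrupted or truncated payloads fail
# with a named field.

PLA_MAGIC <- charToRaw("PLAINDEX")

w_int <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                   endian = "little")
w_dbl <- function(con, x) writeBin(as.numeric(x), con, size = 8,
                                   endian = "little")
w_raw <- function(con, r) {
  w_int(con, length(r))
  writeBin(r, con)
}

r_int <- function(con, field, n = 1) {
  v <- readBin(con, "integer", n = n, size = 4, endian = "little")
  if (length(v) != n) stop("truncated index data while reading ", field)
  v
}
r_dbl <- function(con, field, n = 1) {
  v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(v) != n) stop("truncated index data while reading ", field)
  v
}
r_raw <- function(con, field) {
  len <- r_int(con, field)
  v <- readBin(con, "raw", n = len)
  if (length(v) != len) stop("truncated index data while reading ", field)
  v
}

w_fw <- function(con, s) {
  w_int(con, 1L)
  w_int(con, s$width)
  w_dbl(con, s$n)
  w_raw(con, s$bits)
}
r_fw <- function(con, field) {
  if (r_int(con, field) != 1L) stop("bad sequence tag for ", field,
                                    " (expected fixed-width)")
  width <- r_int(con, field)
  n <- r_dbl(con, field)
  bits <- r_raw(con, field)
  structure(list(width = width, n = n, bits = bits,
                 size_bits = n * width), class = "fw_seq")
}

w_ef <- function(con, s) {
  w_int(con, 2L)
  w_dbl(con, c(s$m, s$U, s$offset))
  w_int(con, s$l)
  w_raw(con, s$low)
  w_raw(con, s$high)
  w_dbl(con, length(s$sel))
  w_dbl(con, s$sel)
  w_dbl(con, c(s$size_bits, s$overhead_bits))
}
r_ef <- function(con, field) {
  if (r_int(con, field) != 2L) stop("bad sequence tag for ", field,
                                    " (expected Elias-Fano)")
  mU <- r_dbl(con, field, 3)
  l <- r_int(con, field)
  low <- r_raw(con, field)
  high <- r_raw(con, field)
  nsel <- r_dbl(con, field)
  sel <- r_dbl(con, field, nsel)
  sz <- r_dbl(con, field, 2)
  structure(list(m = mU[1], U = mU[2], l = l, offset = mU[3], low = low,
                 high = high, sel = sel, size_bits = sz[1],
                 overhead_bits = sz[2]), class = "ef_seq")
}

w_dxu <- function(con, s) {
  w_int(con, 3L)
  w_int(con, c(s$width, s$k))
  w_dbl(con, c(s$bias, s$m, s$U))
  w_fw(con, s$deltas)
}
r_dxu <- function(con, field) {
  if (r_int(con, field) != 3L) stop("bad sequence tag for ", field,
                                    " (expected delta-from-uniform)")
  wk <- r_int(con, field, 2)
  bmU <- r_dbl(con, field, 3)
  deltas <- r_fw(con, field)
  structure(list(width = wk[1], bias = bmU[1], m = bmU[2], U = bmU[3],
                 k = wk[2], deltas = deltas,
                 size_bits = deltas$size_bits), class = "dxu_seq")
}

w_dac <- function(con, s) {
  w_int(con, 4L)
  w_int(con, c(s$width, length(s$layers)))
  w_dbl(con, c(s$n, s$size_bits, s$overhead_bits))
  for (L in s$layers) {
    w_raw(con, L$chunks)
    w_raw(con, L$cont)
    w_dbl(con, length(L$rank))
    w_dbl(con, L$rank)
    w_dbl(con, L$n)
  }
}
r_dac <- function(con, field) {
  if (r_int(con, field) != 4L) stop("bad sequence tag for ", field,
                                    " (expected DAC)")
  wn <- r_int(con, field, 2)
  meta <- r_dbl(con, field, 3)
  layers <- vector("list", wn[2])
  for (i in seq_len(wn[2])) {
    chunks <- r_raw(con, field)
    cont <- r_raw(con, field)
    nr <- r_dbl(con, field)
    rk <- r_dbl(con, field, nr)
    ln <- r_dbl(con, field)
    layers[[i]] <- list(chunks = chunks, cont = cont, rank = rk, n = ln)
  }
  structure(list(width = wn[1], n = meta[1], layers = layers,
                 size_bits = meta[2], overhead_bits = meta[3]),
            class = "dac_seq")
}

serialize_body <- function(con, idx) {
  w_int(con, idx$k)
  w_dbl(con, c(idx$eps, idx$N, if (is.null(idx$n)) NA_real_ else idx$n,
               idx$b, idx$forced, idx$X0, idx$Xb))
  w_int(con, if (idx$x_encoding == "delta") 1L else 2L)
  if (idx$x_encoding == "delta") w_dxu(con, idx$X_enc)
  else w_ef(con, idx$X_enc)
  w_ef(con, idx$Ystart_enc)
  if (idx$variant == "basic") w_fw(con, idx$Yend_enc)
  else w_dac(con, idx$Yend_enc)
  w_dbl(con, c(idx$D$ell, idx$D$bl, idx$D$size_bits))
  w_int(con, idx$D$prefix_bits)
  w_fw(con, idx$D$entries)
}

deserialize_body <- function(con, variant) {
  k <- r_int(con, "k")
  meta <- r_dbl(con, "metadata", 7)
  xe <- r_int(con, "x_encoding")
  if (!xe %in% 1:2) stop("bad x_encoding tag")
  X_enc <- if (xe == 1L) r_dxu(con, "X") else r_ef(con, "X")
  Ystart_enc <- r_ef(con, "Ystart")
  Yend_enc <- if (variant == "basic") r_fw(con, "Yend") else r_dac(con, "Yend")
  Dm <- r_dbl(con, "prefix table", 3)
  pb <- r_int(con, "prefix table")
  ent <- r_fw(con, "prefix table entries")
  D <- structure(list(ell = Dm[1], bl = Dm[2], prefix_bits = pb,
                      entries = ent, size_bits = Dm[3]),
                 class = "prefix_table")
  structure(
    list(k = k, eps = meta[1], variant = variant, N = meta[2], n = meta[3],
         b = as.integer(meta[4]), forced = meta[5],
         x_encoding = if (xe == 1L) "delta" else "ef",
         X_enc = X_enc, Ystart_enc = Ystart_enc, Yend_enc = Yend_enc,
         D = D, X0 = meta[6], Xb = meta[7]),
    class = "pla_index"
  )
}

#' Serialize an index to raw bytes
#'
#' @param idx a `pla_index` or `pla_index_exact`.
#' @return a raw vector; [pla_deserialize()] restores a bit-identical index.
#' @export
pla_serialize <- function(idx) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(PLA_MAGIC, con)
  w_int(con, 1L)  # version
  if (inherits(idx, "pla_index_exact")) {
    w_int(con, 3L)
    serialize_body(con, idx$base)
    w_dbl(con, c(idx$mphf$n, idx$mphf$m, idx$mphf$bits_per_key))
    w_fw(con, idx$mphf$seeds)
    w_fw(con, idx$E)
    w_dbl(con, c(idx$eps, idx$n, idx$N))
    w_int(con, idx$k)
  } else {
    stopifnot(inherits(idx, "pla_index"))
    w_int(con, if (idx$variant == "basic") 1L else 2L)
    serialize_body(con, idx)
  }
  rawConnectionValue(con)
}

#' Restore an index from raw bytes
#'
#' @param bytes a raw vector from [pla_serialize()].
#' @param expect_variant optionally one of `"basic"`, `"repeat"`, `"exact"`;
#'   a file of a different variant is rejected.
#' @return the restored index object.
#' @export
pla_deserialize <- function(bytes, expect_variant = NULL) {
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8)
  if (length(magic) != 8 || !identical(magic, PLA_MAGIC)) {
    stop("bad magic: not a serialized pla_index")
  }
  version <- r_int(con, "version")
  if (version != 1L) stop("unsupported index format version ", version)
  vt <- r_int(con, "variant")
  variant <- c("basic", "repeat", "exact")[vt]
  if (is.na(variant)) stop("bad variant tag ", vt)
  if (!is.null(expect_variant) && variant != expect_variant) {
    stop("index file is '", variant, "' but '", expect_variant,
         "' was requested")
  }
  if (variant == "exact") {
    base <- deserialize_body(con, "basic")
    mm <- r_dbl(con, "mphf", 3)
    seeds <- r_fw(con, "mphf seeds")
    E <- r_fw(con, "error array")
    meta <- r_dbl(con, "exact metadata", 3)
    k <- r_int(con, "k")
    mphf <- structure(list(n = mm[1], m = mm[2], seeds = seeds,
                           bits_per_key = mm[3]), class = "mphf")
    structure(list(base = base, mphf = mphf, E = E, k = k, eps = meta[1],
                   n = meta[2], N = meta[3]), class = "pla_index_exact")
  } else {
    deserialize_body(con, variant)
  }
}

#' Save / load an index file
#'
#' @param idx an index object.
#' @param path file path.
#' @return `pla_save` the path invisibly; `pla_load` the restored index.
#' @export
pla_save <- function(idx, path) {
  writeBin(pla_serialize(idx), path)
  invisible(path)
}

#' @rdname pla_save
#' @param expect_variant see [pla_deserialize()].
#' @export
pla_load <- function(path, expect_variant = NULL) {
  pla_deserialize(readBin(path, "raw", n = file.size(path)), expect_variant)
}
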