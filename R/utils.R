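# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is half-to-even). Values here are non-negative percentages.
roundHalfUp <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical variant key "chrom:pos:ref:alt".
makeKeys <- function(chrom, pos, ref, alt) {
    paste(chrom, pos, ref, alt, sep = ":")
}

splitKeys <- function(keys) {
    parts <- strsplit(keys, ":", fixed = TRUE)
    bad <- lengths(parts) != 4L
    if (any(bad))
        stop("malformed variant key(s): ", paste(keys[bad], collapse = ", "))
    m <- do.call(rbind, parts)
    data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
               ref = m[, 3L], alt = m[, 4L], stringsAsFactors = FALSE)
}

# Exact comparison 100*alt/depth < th for integer counts and a decimal
# threshold: scale th to an integer numerator over 1e6 so grid values such
# as 2.6 do not suffer binary-float boundary artifacts.
altBelowPercent <- function(ref, alt, thPercent) {
    depth <- ref + alt
    num <- round(thPercent * 1e6)
    depth > 0 & (alt * 1e8) < (num * depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
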