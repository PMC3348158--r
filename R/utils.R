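# 32-bit FNV-1a hash, used for config/input provenance fingerprints.
# Exact over double arithmetic (all intermediates < 2^53); the xor with a
# byte only touches the low 8 bits, so it reduces to integer bitwXor there.
.fnv1a <- function(bytes) {
  if (is.character(bytes)) bytes <- charToRaw(paste(bytes, collapse = "\n"))
  h <- 2166136261
  for (b in as.integer(bytes)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # (h * 16777619) mod 2^32, split so every intermediate stays < 2^53
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.file_digest <- function(path) {
  .fnv1a(readBin(path, "raw", n = file.size(path)))
}
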