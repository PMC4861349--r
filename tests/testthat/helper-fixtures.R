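# Fixtures are built in code: small Calpha traces, rigid transforms and
# hand-written fixed-width PDB records.

mk_struct <- function(xyz, resno = seq_len(nrow(xyz)), aa = NULL,
                      id = "fix", model = 1L, chain = "A",
                      method = "SYNTHETIC", ins = NULL) {
  if (is.null(aa)) aa <- rep("A", nrow(xyz))
  calpha_structure(id, model, chain, resno, aa, xyz, method = method,
                   ins = ins)
}

# extended-chain coordinates with mild deterministic wiggle
chain_xyz <- function(n, wiggle = 0) {
  cbind(3.8 * seq_len(n), wiggle * sin(seq_len(n)), wiggle * cos(seq_len(n)))
}

rand_xyz <- function(n, scale = 8) matrix(rnorm(3 * n, 0, scale), ncol = 3)

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rigid_transform <- function(xyz, R = random_rotation(),
                            t = rnorm(3, 0, 10)) {
  sweep(xyz %*% t(R), 2, -t)
}

transform_struct <- function(s, R = random_rotation(), t = rnorm(3, 0, 10)) {
  s$xyz <- rigid_transform(s$xyz, R, t)
  s
}

# hand-written PDB ATOM record (PDB v3.3 fixed columns)
atom_line <- function(serial, resname, chain, resno, x, y, z,
                      occ = 1, altloc = " ", ins = " ") {
  sprintf("ATOM  %5d  CA %1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, altloc, resname, chain, resno, ins, x, y, z, occ, 0)
}

write_fixture <- function(lines, name = "fix.pdb") {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# decoy built from a reference structure by dropping the given residue
# numbers and/or adding coordinate noise
derive_decoy <- function(reference, id, drop = integer(0), sigma = 0) {
  keep <- !(reference$resno %in% drop)
  xyz <- reference$xyz[keep, , drop = FALSE]
  if (sigma > 0) xyz <- xyz + matrix(rnorm(3 * nrow(xyz), 0, sigma), ncol = 3)
  s <- calpha_structure(id, 1L, reference$chain_id, reference$resno[keep],
                        reference$aa[keep], xyz, method = "MODEL",
                        ins = reference$ins[keep])
  decoy_record(id, s)
}
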