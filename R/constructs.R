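#' Reporter construct sequences
#'
#' The three promoter fragments assayed for luciferase activity in the
#' source study, verbatim: the 7d ("down") consensus, the full 7up
#' consensus, and the 7up consensus with the 8-nt SOX2/3-motif insertion
#' deleted. Useful as a small real-sequence fixture: the up-vs-down pair
#' exercises insertion detection and the up/deletion pair differs by
#' exactly 8 nt.
#'
#' @return Named character vector with elements `7down`, `LTR7upcons` and
#'   `LTR7upcons_AAAGAAG_deletion`.
#' @export
reporter_constructs <- function() {
  c(
    "7down" = paste0(
      "GCTAGCTGTCAGGCCTCTGAGCCCAAGCTAAGCCATCATATCCCCTGTGACCTGCACGTACACAT",
      "CCAGATGGCCGGTTCCTGCCTTAACTGATGACATTCCACCACAAAAGAAGTGAAAATGGCCTGTT",
      "CCTGCCTTAACTGATGACATTATCTTGTGAAATTCCTTCTCCTGGCTCATCCTGGCTCAAAAGCT",
      "CCCCTACTGAGCACCTTGTGACCCCCACTCCTGCCCGCCAGAGAACAACCCCCCTTTGACTGTAA",
      "TTTTCCTTTACCTACCCAAATCCTATAAAACGGCCCCACCCCTATCTCCCTTCGCTGACTCTCTT",
      "TTCGGACTCAGCCCGCCTGCACCCAGGTGAAATAAACAGCTTTATTGCTCACACAAAGCCTGTTT",
      "GGTGGTCTCTTCACACGGACGCGCATGCTCGAG"
    ),
    "LTR7upcons" = paste0(
      "GCTAGCTGTCAGGCCTCTGAGCCCAAGCCAAGCCATCGCATCCCCTGTGACTTGCACGTATACGC",
      "CCAGATGGCCTGAAGTAACTGAAGAATCACAAAAGAAGTGAATATGCCCTGCCCCACCTTAACTG",
      "ATGACATTCCACCACAAAAGAAGTGTAAATGGCCGGTCCTTGCCTTAAGTGATGACATTACCTTG",
      "TGAAAGTCCTTTTCCTGGCTCATCCTGGCTCAAAAAGCACCCCCACTGAGCACCTTGCGACCCCC",
      "ACTCCTGCCCGCCAGAGAACAAACCCCCTTTGACTGTAATTTTCCTTTACCTACCCAAATCCTAT",
      "AAAACGGCCCCACCCTTATCTCCCTTCGCTGACTCTCTTTTCGGACTCAGCCCGCCTGCACCCAG",
      "GTGAAATAAACAGCCATGTTGCTCACACAAAGCCTGTTTGGTGGTCTCTTCACACGGACGCGCAT",
      "GCTCGAG"
    ),
    "LTR7upcons_AAAGAAG_deletion" = paste0(
      "GCTAGCTGTCAGGCCTCTGAGCCCAAGCCAAGCCATCGCATCCCCTGTGACTTGCACGTATACGC",
      "CCAGATGGCCTGAAGTAACTGAAGAATCACAAAAGAAGTGAATATGCCCTGCCCCACCTTAACTG",
      "ATGACATTCCACCATTGTAAATGGCCGGTCCTTGCCTTAAGTGATGACATTACCTTGTGAAAGTC",
      "CTTTTCCTGGCTCATCCTGGCTCAAAAAGCACCCCCACTGAGCACCTTGCGACCCCCACTCCTGC",
      "CCGCCAGAGAACAAACCCCCTTTGACTGTAATTTTCCTTTACCTACCCAAATCCTATAAAACGGC",
      "CCCACCCTTATCTCCCTTCGCTGACTCTCTTTTCGGACTCAGCCCGCCTGCACCCAGGTGAAATA",
      "AACAGCCATGTTGCTCACACAAAGCCTGTTTGGTGGTCTCTTCACACGGACGCGCATGCTCGAG"
    )
  )
}
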