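# Orthogonal wavelet scaling (analysis low-pass, dec_lo) filter coefficients.
# One wavelet per line: name followed by whitespace-separated coefficients.
# The remaining three filters of the quadrature-mirror bank are derived:
#   dec_hi[k] = (-1)^(k+1) * dec_lo[L-1-k]   (0-based k)
#   rec_lo    = reverse(dec_lo)
#   rec_hi    = reverse(dec_hi)
# Add a line here to make a new orthogonal wavelet available by name.
haar 0.7071067811865476 0.7071067811865476
db2 -0.12940952255126037 0.2241438680420134 0.8365163037378079 0.48296291314453416
db3 0.03522629188570953 -0.08544127388202666 -0.13501102001025458 0.45987750211849154 0.8068915093110925 0.33267055295008263
db4 -0.010597401785069032 0.0328830116668852 0.030841381835560764 -0.18703481171909309 -0.027983769416859854 0.6308807679298589 0.7148465705529157 0.2303778133088965
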