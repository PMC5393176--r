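# Idealized A-form nucleotide templates (generated; do not edit).
# One full nucleotide per base type, placed at helix index 0 for
# strand 1 and for the strand-2 partner; build_duplex() applies the
# exact screw (AFORM_TWIST deg / AFORM_RISE A about +z) per step.

AFORM_TWIST <- 32.7
AFORM_RISE <- 2.81

AFORM_TORSION_SET <- c(alpha = -41.294, beta = 156.752, gamma = 33.835, delta = 85.769, epsilon = -140.092, zeta = -86.813, chi_purine = -156.730, chi_pyrimidine = -149.094)

AFORM_TEMPLATE_S1 <- list(
  A = matrix(c(
    6.11801, 5.59197, -0.76916,
    5.88866, 4.12591, -0.71190,
    7.07928, 6.18540, 0.19470,
    4.70135, 6.33708, -0.60132,
    4.83434, 7.62143, -1.21061,
    3.44450, 8.13786, -1.60777,
    3.03505, 7.55783, -2.87106,
    2.40067, 7.68047, -0.61880,
    2.32585, 8.58397, 0.48614,
    1.13112, 7.70826, -1.45763,
    0.60371, 9.03453, -1.52389,
    1.65095, 7.22869, -2.82425,
    1.47914, 5.77692, -3.03842,
    2.39513, 4.81769, -2.72520,
    1.89628, 3.63682, -2.94794,
    0.63018, 3.76183, -3.41124,
    -0.36710, 2.85979, -3.81922,
    -0.14529, 1.49432, -3.77885,
    -1.52951, 3.34711, -4.23835,
    -1.74876, 4.64810, -4.27988,
    -0.84353, 5.53039, -3.91408,
    0.34871, 5.13688, -3.48002
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"), NULL)),
  C = matrix(c(
    6.11801, 5.59197, -0.76916,
    5.88866, 4.12591, -0.71190,
    7.07928, 6.18540, 0.19470,
    4.70135, 6.33708, -0.60132,
    4.83434, 7.62143, -1.21061,
    3.44450, 8.13786, -1.60777,
    3.03505, 7.55783, -2.87106,
    2.40067, 7.68047, -0.61880,
    2.32585, 8.58397, 0.48614,
    1.13112, 7.70826, -1.45763,
    0.60371, 9.03453, -1.52389,
    1.65095, 7.22869, -2.82425,
    1.45331, 5.78347, -2.83976,
    0.34080, 5.29273, -3.41245,
    -0.50833, 6.06179, -3.83188,
    0.14908, 3.97943, -3.52997,
    1.05548, 3.12087, -3.08210,
    0.84766, 1.76732, -3.20793,
    2.23114, 3.60388, -2.47190,
    2.41366, 4.94101, -2.36616
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"), NULL)),
  G = matrix(c(
    6.11801, 5.59197, -0.76916,
    5.88866, 4.12591, -0.71190,
    7.07928, 6.18540, 0.19470,
    4.70135, 6.33708, -0.60132,
    4.83434, 7.62143, -1.21061,
    3.44450, 8.13786, -1.60777,
    3.03505, 7.55783, -2.87106,
    2.40067, 7.68047, -0.61880,
    2.32585, 8.58397, 0.48614,
    1.13112, 7.70826, -1.45763,
    0.60371, 9.03453, -1.52389,
    1.65095, 7.22869, -2.82425,
    1.47053, 5.77912, -2.97220,
    2.39055, 4.82156, -2.65815,
    1.89195, 3.64042, -2.88118,
    0.62640, 3.76962, -3.35005,
    -0.37288, 2.85322, -3.75261,
    -0.16977, 1.65156, -3.71471,
    -1.55928, 3.34239, -4.17393,
    -1.77189, 4.68721, -4.21821,
    -2.98487, 5.15550, -4.65746,
    -0.85217, 5.54882, -3.84720,
    0.34461, 5.13826, -3.41245
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"), NULL)),
  U = matrix(c(
    6.11801, 5.59197, -0.76916,
    5.88866, 4.12591, -0.71190,
    7.07928, 6.18540, 0.19470,
    4.70135, 6.33708, -0.60132,
    4.83434, 7.62143, -1.21061,
    3.44450, 8.13786, -1.60777,
    3.03505, 7.55783, -2.87106,
    2.40067, 7.68047, -0.61880,
    2.32585, 8.58397, 0.48614,
    1.13112, 7.70826, -1.45763,
    0.60371, 9.03453, -1.52389,
    1.65095, 7.22869, -2.82425,
    1.46192, 5.78130, -2.90598,
    0.34828, 5.29487, -3.47884,
    -0.49376, 6.06267, -3.90039,
    0.15691, 3.96743, -3.60171,
    1.08151, 3.10206, -3.13861,
    0.90629, 1.90140, -3.24490,
    2.25600, 3.60207, -2.52889,
    2.42511, 4.93766, -2.42368
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"), NULL))
)

AFORM_TEMPLATE_S2 <- list(
  A = matrix(c(
    -7.91196, -2.47005, -7.72706,
    -6.52983, -3.01011, -7.78432,
    -8.90870, -3.00174, -8.69092,
    -7.84237, -0.87089, -7.89490,
    -9.01899, -0.33907, -7.28561,
    -8.76533, 1.12175, -6.88845,
    -8.05803, 1.18344, -5.62516,
    -7.84455, 1.79328, -7.87742,
    -8.58748, 2.31287, -8.98236,
    -7.22930, 2.90413, -7.03859,
    -8.10959, 4.02763, -6.97233,
    -7.07671, 2.21353, -5.67197,
    -5.73591, 1.63095, -5.45780,
    -5.36840, 0.35655, -5.77102,
    -4.09696, 0.19294, -5.54828,
    -3.56745, 1.34976, -5.08498,
    -2.28594, 1.75717, -4.67700,
    -1.21789, 0.87797, -4.71737,
    -2.12165, 3.00685, -4.25787,
    -3.13528, 3.85137, -4.21634,
    -4.35337, 3.51354, -4.58214,
    -4.61372, 2.28533, -5.01620
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"), NULL)),
  C = matrix(c(
    -7.91196, -2.47005, -7.72706,
    -6.52983, -3.01011, -7.78432,
    -8.90870, -3.00174, -8.69092,
    -7.84237, -0.87089, -7.89490,
    -9.01899, -0.33907, -7.28561,
    -8.76533, 1.12175, -6.88845,
    -8.05803, 1.18344, -5.62516,
    -7.84455, 1.79328, -7.87742,
    -8.58748, 2.31287, -8.98236,
    -7.22930, 2.90413, -7.03859,
    -8.10959, 4.02763, -6.97233,
    -7.07671, 2.21353, -5.67197,
    -5.73347, 1.63949, -5.52402,
    -4.75143, 2.35649, -4.95133,
    -4.99165, 3.47666, -4.53190,
    -3.51876, 1.86451, -4.83381,
    -3.22977, 0.64995, -5.28168,
    -1.95420, 0.15173, -5.15585,
    -4.23676, -0.12559, -5.89188,
    -5.48545, 0.38631, -5.99762
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"), NULL)),
  G = matrix(c(
    -7.91196, -2.47005, -7.72706,
    -6.52983, -3.01011, -7.78432,
    -8.90870, -3.00174, -8.69092,
    -7.84237, -0.87089, -7.89490,
    -9.01899, -0.33907, -7.28561,
    -8.76533, 1.12175, -6.88845,
    -8.05803, 1.18344, -5.62516,
    -7.84455, 1.79328, -7.87742,
    -8.58748, 2.31287, -8.98236,
    -7.22930, 2.90413, -7.03859,
    -8.10959, 4.02763, -6.97233,
    -7.07671, 2.21353, -5.67197,
    -5.72856, 1.65656, -5.65646,
    -5.36833, 0.37845, -5.97051,
    -4.09729, 0.21069, -5.74748,
    -3.56821, 1.36758, -5.27861,
    -2.27209, 1.76564, -4.87605,
    -1.33850, 0.98229, -4.91395,
    -2.09355, 3.03644, -4.45473,
    -3.14581, 3.90043, -4.41045,
    -2.93580, 5.18360, -3.97120,
    -4.35440, 3.54327, -4.78146,
    -4.60601, 2.30330, -5.21621
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"), NULL)),
  U = matrix(c(
    -7.91196, -2.47005, -7.72706,
    -6.52983, -3.01011, -7.78432,
    -8.90870, -3.00174, -8.69092,
    -7.84237, -0.87089, -7.89490,
    -9.01899, -0.33907, -7.28561,
    -8.76533, 1.12175, -6.88845,
    -8.05803, 1.18344, -5.62516,
    -7.84455, 1.79328, -7.87742,
    -8.58748, 2.31287, -8.98236,
    -7.22930, 2.90413, -7.03859,
    -8.10959, 4.02763, -6.97233,
    -7.07671, 2.21353, -5.67197,
    -5.73102, 1.64803, -5.59024,
    -4.75000, 2.36525, -5.01738,
    -4.98936, 3.47937, -4.59583,
    -3.50677, 1.86218, -4.89451,
    -3.22468, 0.62761, -5.35761,
    -2.09911, 0.17441, -5.25132,
    -4.24807, -0.13535, -5.96733,
    -5.48714, 0.39106, -6.07253
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"), NULL))
)
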