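# The Metropolis kernel is the package's hot path; build it optimized for
# the host it is compiled on. CXXFLAGS (not PKG_CXXFLAGS) because the
# site-wide CXXFLAGS would otherwise override the optimization level.
CXXFLAGS = -O3 -funroll-loops -march=native -fPIC
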