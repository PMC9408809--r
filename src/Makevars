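# Build with the system toolchain so the shared object links against the
# glibc the R process actually runs under.
override CXX = /usr/bin/g++
override CXX17 = /usr/bin/g++
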