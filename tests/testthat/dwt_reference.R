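x <- c(0.30471707975443135, -1.0399841062404955, 0.75045119580645725, 0.94056471639121386, -1.9510351886538364, -1.3021795068623181, 0.12784040316728537, -0.31624259234358221, -0.016801157504288795, -0.85304392757358005, 0.87939797486282856, 0.77779193542894831, 0.066030697561216045, 1.1272412069680329, 0.4675093422520456, -0.85929246288323824, 0.36875078408249884, -0.9588826008289989, 0.87845030130727253, -0.049925910986252896, -0.18486236354526056, -0.68092954440394138, 1.2225413386740303, -0.15452948206880215, -0.42832782216310722, -0.35213355048822959, 0.53230918555334872, 0.36544406436407834, 0.4127326115959884, 0.43082100300788273, 2.1416476008704612, -0.40641501638461558, -0.51224272907153734, -0.81377272824787772, 0.61597942257549565, 1.1289722927208916, -0.11394745765487507, -0.84015647696252804, -0.82448121569123956, 0.65059278782470109, 0.74325417120344228, 0.54315426830519498, -0.6655097072886943, 0.23216132306671977, 0.11668580914072822, 0.21868859672901295, 0.87142877794818985, 0.22359554877468227, 0.67891356307189488, 0.067579069488891461, 0.28911939868998415, 0.63128822583854038, -1.4571558198556664, -0.31967121635730134, -0.47037265429279551, -0.63887784824334193, -0.27514225122668373, 1.4949413112343959, -0.86583111569324323, 0.96827835459148082, -1.6828697716158048)
A5 <- c(-0.82341063589625718, -0.93689440543423641, 1.0369830840586909, -2.3571987144820126)
D5 <- c(0.12692944977650422, -0.0034667359874483022, 1.8823056726827228, -2.1320999303569503)
D4 <- c(0.057129335609871899, -0.58449666094137909, -0.10982614782009122, -0.19469760289847607, 0.70891629041031035, -1.2538833648391974)
D3 <- c(-0.092049444089125743, -0.65279832062579612, 1.6385460157604457, 0.013667884491387589, 1.2783901114459928, -0.66598212342669361, -0.1894854603480996, -1.2965248993603244, -0.65983965514869558, 1.5486971748332996)
D2 <- c(0.38690729822864445, 1.8414187993433668, 0.54734885429079294, 0.36736322565165813, -0.42542852756103539, 0.6665695475355603, 0.57722131090689777, 0.017058377044282015, 0.7025937085157441, 1.7255825731741969, -0.044845850979632923, -0.47763033998117288, 0.37681166509913322, 0.62035957364481886, -1.0627726263478685, 1.0605345429263733, -1.3005700432986929)
D1 <- c(0.82345794055073707, 0.36717955349309794, -1.3111056810268678, 0.80403210898204702, 0.45227421047807187, 0.55336487979870863, -0.77731970707517672, 0.54487637266951883, 0.90367575280199752, 0.92615815471771734, 0.071734088085186734, 1.2738569027718112, -0.31180741632377906, 0.40314765746346454, -0.013610931663876724, 1.8378290989920016, -0.22153150656621207, 0.21871633641554106, -0.022320306066322071, -0.80084235853195251, 0.32029020081706722, -0.88676389542168754, 0.026076856524855863, 0.55685805988067338, 0.3723953267993772, -0.16604102393841191, -1.243459446628927, 0.17530209444909794, -0.74809093692729756, -1.4914002800601449, -0.69997117812929921, 1.823129261780279)
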