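{"feature_names":["FR1/12/S","FR1/12/L","FR1/15/P","FR1/15/A","FR1/17/D","FR2/44/F","FR2/44/Y","FR2/51/E","FR2/51/Q","FR2/54/F","FR2/54/G","FR2/54/L","FR2/54/W","FR2/56/A","FR3/85/S","FR3/85/A","FR3/103/V","FR3/103/I","FR3/107/A","FR3/107/N"],"mu":[0.149891435464415,-0.115681544028951,-0.225983112183353,0.213148371531966,0.139927623642943,1.01457177322075,-0.85205066344994,0.464656212303981,-0.444149577804584,0.462195416164053,0.338564535585042,-0.465741857659831,-0.16043425814234,-0.144993968636912,-0.164861278648975,0.16642943305187,-0.213739445114596,0.125934861278649,0.797587454764777,-0.359059107358263],"sigma":[0.385471181384248,0.0530715942429422,0.283016710905302,0.188698449307077,0.552648864743425,0.846505728298909,1.27912613298954,0.344659789934529,0.985909255319709,0.59994323840063,0.796471530128964,0.934866151233248,0.367229876516882,0.0893598068728423,0.50827394408009,0.0852067046322747,0.127748090166693,0.408591903465927,0.566874615414098,0.869064454856679],"w":[0.106168048824508,0.0132649092874465,0.0441277513268867,0.00466579287699521,0.132164682764052,0.34461623651553,0.413634480746601,0.171425304319471,0.312673858957342,0.290532730831629,0.340585621853429,0.314171241835697,0.00593512510885019,0.215159308506527,0.212115569928177,0.0479519819848643,0.0608174967486632,0.0354737512379845,0.505645463853534,0.0821908760577914],"b":0.277649790400208}
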