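sample_id,group,day,replicate,tube,run_id,mix_fraction,role,met_0001,met_0002,met_0003,met_0004,met_0005,met_0006,met_0007,met_0008,met_0009,met_0010,istd_001,istd_002
control_pool_d01_r01,control_pool,1,1,,,,,3886451.8506394676,480631.4736068004,1393216.4903574185,1575221.6873944835,1319520.7863953842,824578.6843806815,4912825.9867322305,739850.4264967369,9490719.678300584,1012642.4721287261,4762029.593917506,14343029.301371023
control_pool_d01_r02,control_pool,1,2,,,,,4757365.691736724,452372.73561155767,1541624.4284034267,1696534.0889512287,1255927.5101873793,888035.8797922449,5715390.850492307,721333.6446407208,8077555.0981563,929506.1617149516,4784679.929505358,13852984.473930579
control_pool_d02_r01,control_pool,2,1,,,,,5180981.947681568,487589.2733470769,1472464.0722514591,2196550.2901604413,1672899.9924010476,971152.2369504939,6857452.392252097,880698.4738737533,10516641.139140872,800185.7811161422,4634066.165989581,13337373.586775307
control_pool_d02_r02,control_pool,2,2,,,,,4767794.899225128,458962.8694220886,1644524.0707396327,2064531.756430243,1528492.3051501755,829203.8163522382,7164101.214473889,851077.5708204944,11433869.465487722,798371.8591834333,4051542.3534197505,14973178.635388443
cfs_pool_d01_r01,cfs_pool,1,1,,,,,5207278.829957283,505808.77189814806,1468923.4024250188,1968928.285300634,1598475.5251035974,1154629.3625768702,5037656.901156844,832836.2588417938,9153173.194758521,738229.9623998429,4752369.341483535,14766010.880786462
cfs_pool_d01_r02,cfs_pool,1,2,,,,,5396744.534152712,508655.9805524116,1587139.896340809,1743896.1905508044,1516533.404952791,958273.9834976161,5809803.110983131,794943.3212988155,10221390.706251867,894173.2190168079,5237434.669843942,14656779.65116789
cfs_pool_d02_r01,cfs_pool,2,1,,,,,5460292.118526337,583741.8167452253,1369341.877871276,2363111.0378294704,1513760.239117506,814363.9116150772,5658683.973103663,866373.5063906477,10855431.370162241,995545.8854101727,4522861.88619516,14875793.335585171
cfs_pool_d02_r02,cfs_pool,2,2,,,,,5798907.45644987,494034.1803059257,1413452.3827784143,2115304.6165157054,1660655.954120458,852168.0728371727,5649006.863724142,792336.7276143405,11186150.232388128,864259.4918618882,4505348.717373273,16893077.851368662
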